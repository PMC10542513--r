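// Path-guided SGD hot loop.
//
// One call performs one iteration (epoch) of term updates on the layout
// passed from R, mutating it in place. Coordinates live in an array of
// std::atomic<double> while the iteration runs so that multi-threaded
// (HOGWILD-style, lock-free) updates are torn-write-free at the
// granularity of a single coordinate; the result is copied back afterwards.
// R's RNG cannot be touched off the main thread, so the engine uses its own
// xoshiro256** streams, seeded deterministically from (seed, iter, thread).

#include <Rcpp.h>
#include <atomic>
#include <cmath>
#include <cstdint>
#include <memory>
#include <vector>
#ifdef _OPENMP
#include <omp.h>
#endif

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double u01() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in [0, n)
  int64_t below(int64_t n) {
    return static_cast<int64_t>(u01() * static_cast<double>(n)) % n;
  }
};

// atomic max for the |r| diagnostic
inline void atomic_max(std::atomic<double>& target, double v) {
  double cur = target.load(std::memory_order_relaxed);
  while (v > cur &&
         !target.compare_exchange_weak(cur, v, std::memory_order_relaxed)) {
  }
}

} // namespace

// [[Rcpp::export]]
double pgsgd_iter_cpp(int dims, Rcpp::NumericVector coords,
                      Rcpp::LogicalVector frozen,
                      Rcpp::IntegerVector step_node,  // 0-based node rank
                      Rcpp::LogicalVector step_rev,
                      Rcpp::NumericVector step_len,
                      Rcpp::NumericVector step_off,
                      Rcpp::IntegerVector ptr0,       // 0-based, length P+1
                      double eta, double theta, int window,
                      double flip_prob, double n_updates,
                      int threads, int seed, int iter) {
  const int n_paths = ptr0.size() - 1;
  const int64_t total_steps = ptr0[n_paths];
  const int64_t ncoord = coords.size();
  const int64_t npoints = (dims == 2) ? ncoord / 2 : ncoord;
  const int64_t nnodes = (dims == 2) ? npoints / 2 : npoints;
  if (total_steps < 1) Rcpp::stop("index has no steps");

  // per-path Zipf inverse-CDF tables, window capped at path steps - 1
  std::vector<std::vector<double>> cdf(n_paths);
  for (int p = 0; p < n_paths; ++p) {
    int64_t m = ptr0[p + 1] - ptr0[p];
    if (m < 2) continue;
    int64_t w = std::min<int64_t>(window, m - 1);
    std::vector<double>& c = cdf[p];
    c.resize(w);
    double h = 0.0;
    for (int64_t k = 1; k <= w; ++k) {
      h += std::pow(static_cast<double>(k), -theta);
      c[k - 1] = h;
    }
    for (int64_t k = 0; k < w; ++k) c[k] /= h;
  }

  std::unique_ptr<std::atomic<double>[]> pos(new std::atomic<double>[ncoord]);
  for (int64_t i = 0; i < ncoord; ++i)
    pos[i].store(coords[i], std::memory_order_relaxed);
  std::atomic<double> max_r(0.0);

  const int nthreads = std::max(1, threads);
  const int64_t total_updates = static_cast<int64_t>(n_updates);

  // copy the index views into plain pointers usable off the main thread
  const int* sn = step_node.begin();
  const int* sr = step_rev.begin();
  const double* sl = step_len.begin();
  const double* so = step_off.begin();
  const int* pp = ptr0.begin();
  const int* fz = frozen.begin();

#ifdef _OPENMP
#pragma omp parallel num_threads(nthreads)
#endif
  {
#ifdef _OPENMP
    const int tid = omp_get_thread_num();
    const int nth = omp_get_num_threads();
#else
    const int tid = 0;
    const int nth = 1;
#endif
    int64_t share = total_updates / nth + (tid < total_updates % nth ? 1 : 0);
    uint64_t sd = static_cast<uint64_t>(static_cast<uint32_t>(seed));
    sd = sd * 2654435761ULL + static_cast<uint64_t>(iter) * 97531ULL +
         static_cast<uint64_t>(tid);
    Xoshiro rng(sd);
    double local_max = 0.0;

    for (int64_t u = 0; u < share; ++u) {
      // anchor: uniform over all steps of all paths
      int64_t flat = rng.below(total_steps);
      int p = static_cast<int>(
          std::upper_bound(pp, pp + n_paths + 1, flat) - pp) - 1;
      int64_t ra = flat - pp[p];
      int64_t m = pp[p + 1] - pp[p];
      int64_t rb;
      if (m == 1) {
        rb = ra;
      } else if (rng.u01() < flip_prob) { // flip: uniform partner
        rb = rng.below(m);
      } else {                            // Zipfian partner
        const std::vector<double>& c = cdf[p];
        double uu = rng.u01();
        int64_t k = static_cast<int64_t>(
            std::lower_bound(c.begin(), c.end(), uu) - c.begin()) + 1;
        if (k > static_cast<int64_t>(c.size())) k = c.size();
        int dir = rng.u01() < 0.5 ? -1 : 1;
        int64_t t = ra + dir * k;
        if (t < 0 || t > m - 1) t = ra - dir * k;
        if (t < 0) t = 0;
        if (t > m - 1) t = m - 1;
        rb = t;
      }

      // resolve ends and nucleotide distance (mirrors term_from_steps())
      int64_t ia = pp[p] + ra, ib = pp[p] + rb;
      int na = sn[ia], nb = sn[ib];
      double oa = so[ia], la = sl[ia], ob = so[ib], lb = sl[ib];
      bool reva = sr[ia] != 0, revb = sr[ib] != 0;
      double pos_a, pos_b;
      bool a_start_end, b_start_end; // which physical node end participates
      if (ra == rb) {
        if (dims == 1) continue;     // a node is a point in 1D
        a_start_end = true; b_start_end = false;
        pos_a = reva ? oa + la : oa;
        pos_b = revb ? ob : ob + lb;
      } else {
        double ca = oa + la / 2, cb = ob + lb / 2;
        if (ca < cb) { pos_a = oa + la; pos_b = ob; }
        else if (ca > cb) { pos_a = oa; pos_b = ob + lb; }
        else {
          pos_a = reva ? oa + la : oa;
          pos_b = revb ? ob + lb : ob;
        }
        a_start_end = (pos_a == (reva ? oa + la : oa));
        b_start_end = (pos_b == (revb ? ob + lb : ob));
      }
      double nd = std::fabs(pos_a - pos_b);

      double wt = 1.0 / std::pow(std::max(nd, 1.0), 2.0);
      double mu = std::min(eta * wt, 1.0);

      if (dims == 1) {
        if (na == nb) continue;
        double xa = pos[na].load(std::memory_order_relaxed);
        double xb = pos[nb].load(std::memory_order_relaxed);
        double ld = std::fabs(xb - xa);
        double s = (ld == 0.0) ? (rng.u01() < 0.5 ? -1.0 : 1.0)
                               : (xb > xa ? 1.0 : -1.0);
        double r = mu * (ld - nd) / 2.0;
        if (!fz[na]) pos[na].store(xa + r * s, std::memory_order_relaxed);
        if (!fz[nb]) pos[nb].store(xb - r * s, std::memory_order_relaxed);
        double ar = std::fabs(r);
        if (ar > local_max) local_max = ar;
      } else {
        int64_t i = 2 * static_cast<int64_t>(na) + (a_start_end ? 0 : 1);
        int64_t j = 2 * static_cast<int64_t>(nb) + (b_start_end ? 0 : 1);
        double ax = pos[i].load(std::memory_order_relaxed);
        double ay = pos[i + npoints].load(std::memory_order_relaxed);
        double bx = pos[j].load(std::memory_order_relaxed);
        double by = pos[j + npoints].load(std::memory_order_relaxed);
        double dx = bx - ax, dy = by - ay;
        double ld = std::sqrt(dx * dx + dy * dy);
        double ux, uy;
        if (ld < 1e-9) {
          double ang = rng.u01() * 6.283185307179586;
          ux = std::cos(ang); uy = std::sin(ang);
        } else {
          ux = dx / ld; uy = dy / ld;
        }
        double r = mu * (ld - nd) / 2.0;
        if (!fz[na]) {
          pos[i].store(ax + r * ux, std::memory_order_relaxed);
          pos[i + npoints].store(ay + r * uy, std::memory_order_relaxed);
        }
        if (!fz[nb]) {
          pos[j].store(bx - r * ux, std::memory_order_relaxed);
          pos[j + npoints].store(by - r * uy, std::memory_order_relaxed);
        }
        double ar = std::fabs(r);
        if (ar > local_max) local_max = ar;
      }
    }
    atomic_max(max_r, local_max);
  }

  bool bad = false;
  for (int64_t i = 0; i < ncoord; ++i) {
    double v = pos[i].load(std::memory_order_relaxed);
    if (!std::isfinite(v)) bad = true;
    coords[i] = v;
  }
  if (bad) Rcpp::stop("layout corrupted: non-finite coordinates after update");
  (void)nnodes;
  return max_r.load(std::memory_order_relaxed);
}
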