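#' Zipf distribution specification
#'
#' Discrete power law over ranks 1..N: P(k) proportional to k^-theta. Used
#' to bias partner sampling toward nearby steps, producing the mostly-local
#' updates that refine a layout, while the long tail still reaches
#' long-range structure.
#'
#' @param theta exponent, > 0.
#' @param window maximum rank N, >= 1. Capped at (path step count - 1) when
#'   sampling on a concrete path.
#' @return object of class `zipf_spec`.
#' @export
zipf_spec <- function(theta = 0.99, window = 10000L) {
  stopifnot(theta > 0, window >= 1)
  structure(list(theta = as.double(theta), window = as.integer(window)),
            class = "zipf_spec")
}

#' Zipf probabilities / CDF
#'
#' @param spec a [zipf_spec()].
#' @return numeric vector of probabilities of ranks `1:window`.
#' @export
zipf_probs <- function(spec) {
  p <- seq_len(spec$window)^(-spec$theta)
  p / sum(p)
}

#' Draw ranks from a Zipf distribution
#'
#' Inverse-CDF sampling on a precomputed table. Uses R's RNG.
#'
#' @param n number of draws.
#' @param spec a [zipf_spec()].
#' @return integer vector of ranks in `[1, window]`.
#' @export
zipf_sample <- function(n, spec) {
  if (spec$window == 1L) return(rep(1L, n))
  cdf <- cumsum(zipf_probs(spec))
  findInterval(stats::runif(n), cdf) + 1L
}

#' Sampler configuration for path-guided SGD terms
#'
#' Holds the Zipf law, the flip probability (per-term chance of uniform
#' rather than Zipfian partner sampling: uniform draws favor global layout
#' moves, Zipfian draws local refinement), and the cooling mechanics (after
#' `cooling_start` of the run, the skewed `cooled_zipf` law replaces `zipf`,
#' increasing the likelihood of small nucleotide distances and hence local
#' linearity/planarity).
#'
#' @param zipf Zipf law for the main phase; default theta 0.99, window 10000.
#' @param flip_probability probability of uniform partner sampling, in
#'   `[0,1]`; default 0.5 ("half of the updates" in expectation).
#' @param cooling_start fraction of total iterations after which cooling is
#'   active; default 0.5.
#' @param cooled_zipf skewed law for the cooling phase; default theta 2,
#'   window 100.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(zipf = zipf_spec(0.99, 10000L),
                           flip_probability = 0.5,
                           cooling_start = 0.5,
                           cooled_zipf = zipf_spec(2.0, 100L)) {
  stopifnot(inherits(zipf, "zipf_spec"), inherits(cooled_zipf, "zipf_spec"),
            flip_probability >= 0, flip_probability <= 1,
            cooling_start >= 0, cooling_start <= 1)
  structure(list(zipf = zipf, flip_probability = flip_probability,
                 cooling_start = cooling_start, cooled_zipf = cooled_zipf),
            class = "sampler_config")
}

#' Sample partner steps on the same path
#'
#' Given an anchor step `si`, draws partner steps `sj` from the same path.
#' Uniform mode draws from all steps of the path. Zipf mode draws a rank
#' distance k from the Zipf law (window capped at path step count - 1) and a
#' direction with probability 1/2 each; if rank(si) +/- k falls off the
#' path the direction is flipped, and if both directions fall off, k is
#' clamped to the boundary in the original direction. On a single-step path
#' the anchor itself is returned.
#'
#' @param index a `path_index`.
#' @param path,rank the anchor step (1-based path, 0-based rank), scalars.
#' @param mode `"uniform"` or `"zipf"`.
#' @param spec a [zipf_spec()] (zipf mode only).
#' @param n number of partner draws for this anchor.
#' @return integer vector of partner ranks (0-based), length `n`.
#' @export
sample_partner <- function(index, path, rank, mode = c("zipf", "uniform"),
                           spec = zipf_spec(), n = 1L) {
  mode <- match.arg(mode)
  check_step_ref(index, path, rank)
  m <- index$path_steps[path]
  if (m == 1L) return(rep(0L, n))
  if (mode == "uniform") {
    return(sample.int(m, n, replace = TRUE) - 1L)
  }
  w <- min(spec$window, m - 1L)
  k <- zipf_sample(n, zipf_spec(spec$theta, w))
  dir <- ifelse(stats::runif(n) < 0.5, -1L, 1L)
  target <- rank + dir * k
  out <- target < 0L | target > m - 1L
  target[out] <- rank - dir[out] * k[out]
  still <- target < 0L | target > m - 1L
  target[still] <- ifelse(dir[still] > 0L, m - 1L, 0L)  # unreachable when k <= m-1
  as.integer(target)
}

# Resolve a pair of steps on one path into a term: which node end of each
# step participates (the end nearer the other step along the path; tie ->
# sequence-start end), the path coordinates of those ends, and nd.
# Vectorized over ra/rb. A step's interval is [off, off+len); "nearer" is
# decided on interval midpoints. si == sj joins the two ends of that node
# with nd = node length.
term_from_steps <- function(index, path, ra, rb) {
  ia <- index$ptr[path] + ra
  ib <- index$ptr[path] + rb
  oa <- index$step_off[ia]; la <- index$step_len[ia]; reva <- index$step_rev[ia]
  ob <- index$step_off[ib]; lb <- index$step_len[ib]; revb <- index$step_rev[ib]
  ca <- oa + la / 2; cb <- ob + lb / 2

  # end choice encoded as the path coordinate of the chosen end:
  # left (ca < cb): a uses its right edge (oa+la), b its left edge (ob)
  a_right <- ca < cb
  b_right <- cb < ca
  tie <- ca == cb
  pos_a <- ifelse(a_right, oa + la, oa)
  pos_b <- ifelse(b_right, ob + lb, ob)
  # path coordinate of a node's sequence-start end: off (fwd) / off+len (rev)
  pos_a[tie] <- ifelse(reva[tie], oa[tie] + la[tie], oa[tie])
  pos_b[tie] <- ifelse(revb[tie], ob[tie] + lb[tie], ob[tie])
  # which physical node end sits at that coordinate
  end_a <- ifelse(pos_a == ifelse(reva, oa + la, oa), "start", "end")
  end_b <- ifelse(pos_b == ifelse(revb, ob + lb, ob), "start", "end")

  same <- ra == rb
  end_a[same] <- "start"; end_b[same] <- "end"
  pos_a[same] <- ifelse(reva[same], oa[same] + la[same], oa[same])
  pos_b[same] <- ifelse(revb[same], ob[same], ob[same] + lb[same])

  list(path = path, rank_a = ra, rank_b = rb,
       node_a = index$step_node[ia], end_a = end_a,
       node_b = index$step_node[ib], end_b = end_b,
       pos_a = pos_a, pos_b = pos_b,
       nd = abs(pos_a - pos_b))
}

#' Sample one SGD term
#'
#' The unit work item of path-guided SGD: an anchor step drawn uniformly
#' from all steps of all paths; a partner step on the same path, uniform
#' with probability `flip_probability` and Zipfian otherwise (the cooled
#' Zipf law once `progress >= cooling_start`); one node end per step (the
#' end nearer the other step); and the nucleotide distance `nd` between the
#' two chosen ends in path coordinates. If the anchor and partner are the
#' same step (always on a 1-step path), the term joins the node's two ends
#' with `nd` = node length.
#'
#' @param index a `path_index`.
#' @param config a [sampler_config()].
#' @param progress fraction of the run completed, in `[0,1]`.
#' @return a list with fields `path`, `rank_a`, `rank_b`, `node_a`, `end_a`,
#'   `node_b`, `end_b`, `pos_a`, `pos_b`, `nd`, `mode`.
#' @export
sample_term <- function(index, config = sampler_config(), progress = 0) {
  flat <- sample.int(index$total_steps, 1L)
  path <- findInterval(flat, index$ptr)
  ra <- flat - index$ptr[path]
  mode <- if (stats::runif(1) < config$flip_probability) "uniform" else "zipf"
  spec <- if (progress >= config$cooling_start) config$cooled_zipf else config$zipf
  rj <- sample_partner(index, path, ra, mode, spec, n = 1L)
  t <- term_from_steps(index, path, ra, rj)
  t$mode <- mode
  t
}

# Vectorized unbiased term sampler used for evaluation: anchors uniform over
# all steps, partners uniform over the anchor's path (no Zipf bias).
sample_terms_uniform <- function(index, n) {
  si <- sample_global_step(index, n)
  m <- index$path_steps[si$path]
  rj <- as.integer(floor(stats::runif(n) * m))
  rj[rj >= m] <- m[rj >= m] - 1L  # guard runif() == 1
  term_from_steps(index, si$path, si$rank, rj)
}
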