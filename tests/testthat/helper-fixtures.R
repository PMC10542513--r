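# Shared fixtures and independent oracles. Everything is generated in code;
# seeds are fixed so expected values frozen in the tests are reproducible.

tiny_gfa <- paste(
  "H\tVN:Z:1.0",
  "S\t1\tACG",
  "S\t2\tT",
  "L\t1\t+\t2\t+\t0M",
  "P\tp\t1+,2+\t*",
  sep = "\n")

# linear path with node lengths (3,5,2) -- the worked fixture
graph_352 <- function() {
  variation_graph(
    nodes = data.frame(id = 1:3, sequence = c("ACG", "TTTTT", "CA")),
    edges = data.frame(from = 1:2, from_rev = FALSE, to = 2:3, to_rev = FALSE),
    paths = list(list(name = "p", node_id = 1:3, is_reverse = rep(FALSE, 3))))
}

# the standard fixture family used by round-trip / property tests
fixture_graphs <- function() {
  list(
    linear1 = make_linear(1, seed = 11),
    linear = make_linear(25, seed = 12),
    snp = make_snp_bubbles(12, 0.6, n_paths = 2, seed = 13),
    indel = make_indel_bubbles(10, 0.5, n_paths = 2, seed = 14),
    inv = make_inversion(15, 5, seed = 15),
    tandem = make_tandem_loop(15, 4, 3, seed = 16),
    shuffled = shuffle_ids(make_linear(20, seed = 17), seed = 18))
}

# brute-force path offsets: naive per-step re-scan of the graph
naive_offsets <- function(g, path_name) {
  p <- g$paths[[path_name]]
  len <- nchar(g$nodes$sequence)[match(p$node_id, g$nodes$id)]
  sapply(seq_along(len), function(k) if (k == 1) 0 else sum(len[seq_len(k - 1)]))
}

# build a one-row term by hand (for update-rule unit tests); a plain list
# with the term fields, which the update ops accept like a data.frame row
manual_term <- function(node_a, end_a, node_b, end_b, nd,
                        rank_a = 0L, rank_b = 1L) {
  list(path = 1L, rank_a = rank_a, rank_b = rank_b,
       node_a = node_a, end_a = end_a, node_b = node_b, end_b = end_b,
       pos_a = 0, pos_b = nd, nd = nd)
}

# Independent full-batch SGD MDS oracle: iterates over the exhaustive set of
# all step-pair terms of one path in random order, with the same geometric
# annealing and weighting scheme, using its own inline update arithmetic.
full_batch_sgd_mds <- function(g, iter_max = 30L, seed = 1L) {
  index <- build_path_index(g)
  terms <- pathsgd:::all_step_pair_terms(index, 1L)
  set.seed(seed)
  layout <- init_layout_2d(g, "order_gaussian", sigma = 1)
  xy <- unclass(layout)
  eta_max <- max(index$path_len)^2
  eta_min <- 0.01
  for (t in seq_len(iter_max) - 1L) {
    eta <- eta_max * (eta_min / eta_max)^(t / (iter_max - 1L))
    for (k in sample.int(length(terms$nd))) {
      i <- 2L * (terms$node_a[k] - 1L) + ifelse(terms$end_a[k] == "start", 1L, 2L)
      j <- 2L * (terms$node_b[k] - 1L) + ifelse(terms$end_b[k] == "start", 1L, 2L)
      nd <- terms$nd[k]
      mu <- min(eta / max(nd, 1)^2, 1)
      d <- xy[j, ] - xy[i, ]
      ld <- sqrt(sum(d * d))
      u <- if (ld < 1e-9) {
        ang <- runif(1) * 2 * pi
        c(cos(ang), sin(ang))
      } else d / ld
      r <- mu * (ld - nd) / 2
      xy[i, ] <- xy[i, ] + r * u
      xy[j, ] <- xy[j, ] - r * u
    }
  }
  structure(xy, node_id = attr(layout, "node_id"),
            frozen = attr(layout, "frozen"), class = "layout_2d")
}

# Two stress values agree within a relative tolerance; values below `floor`
# count as converged-to-exact and always agree (normalized stress 1e-4 means
# a typical relative residual of 1%).
stress_agrees <- function(a, b, rel, floor = 1e-4) {
  (a < floor && b < floor) || abs(a - b) <= rel * max(a, b)
}

# Quality gate against the brute-force oracle: the sampled method passes if
# it is within `rel` of the oracle's stress -- doing strictly better than
# the oracle also passes (the comparison bounds PG-SGD's loss of quality,
# not the oracle's).
oracle_agrees <- function(s_method, s_oracle, rel = 0.10, floor = 1e-4) {
  s_method <= (1 + rel) * s_oracle || stress_agrees(s_method, s_oracle, rel, floor)
}
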