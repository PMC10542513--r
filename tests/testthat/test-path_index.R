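test_that("offsets are prefix sums of step node lengths", {
  idx <- build_path_index(graph_352())
  expect_equal(idx$step_off, c(0, 3, 8))
  expect_equal(idx$path_len, 10)
  expect_equal(idx$total_steps, 3L)
})

test_that("flat enumeration covers every step of every path exactly once", {
  g <- variation_graph(
    nodes = data.frame(id = 1:3, sequence = c("AC", "G", "TT")),
    edges = data.frame(from = c(1, 2, 1), from_rev = FALSE,
                       to = c(2, 3, 3), to_rev = FALSE),
    paths = list(list(name = "a", node_id = c(1L, 2L), is_reverse = c(FALSE, FALSE)),
                 list(name = "b", node_id = c(1L, 2L, 3L), is_reverse = rep(FALSE, 3))))
  idx <- build_path_index(g)
  expect_equal(idx$total_steps, 5L)
  refs <- pathsgd:::flat_to_step(idx, seq_len(idx$total_steps))
  expect_equal(paste(refs$path, refs$rank),
               c("1 0", "1 1", "2 0", "2 1", "2 2"))
})

test_that("offsets of a long synthetic path match a naive re-scan", {
  g <- make_linear(1000, seed = 21)
  idx <- build_path_index(g)
  expect_equal(idx$total_steps, 1000L)
  expect_equal(idx$step_off, unname(naive_offsets(g, "p")))
  # multi-visit steps (tandem repeat) also re-scan correctly
  gt <- make_tandem_loop(100, 30, 3, seed = 21)
  it <- build_path_index(gt)
  expect_equal(it$step_off, unname(naive_offsets(gt, "p")))
})

test_that("step_offset answers point queries and rejects bad refs", {
  idx <- build_path_index(graph_352())
  expect_equal(step_offset(idx, 1, 0), 0)
  expect_equal(step_offset(idx, 1, 2), 8)
  expect_error(step_offset(idx, 1, 3), "out of range")
  expect_error(step_offset(idx, 2, 0), "out of range")

  g <- make_linear(50, seed = 22)
  idx <- build_path_index(g)
  off <- naive_offsets(g, "p")
  set.seed(1)
  ranks <- sample(0:49, 20, replace = TRUE)
  expect_equal(step_offset(idx, rep(1, 20), ranks), unname(off[ranks + 1]))
})

test_that("graphs without paths are rejected", {
  g <- variation_graph(data.frame(id = 1L, sequence = "A"))
  expect_error(build_path_index(g), "requires embedded paths")
})

test_that("step_end_offsets swaps ends on the reverse strand", {
  doc <- "S\t1\tAAA\nS\t2\tCCCCC\nL\t1\t+\t2\t-\t0M\nP\tp\t1+,2-\t*"
  idx <- build_path_index(parse_gfa(doc))
  expect_equal(step_end_offsets(idx, 1, 0), cbind(start = 0, end = 3))
  expect_equal(step_end_offsets(idx, 1, 1), cbind(start = 8, end = 3))
})

test_that("|start - end| equals node length on random graphs", {
  for (g in list(fixture_graphs()$inv, fixture_graphs()$tandem)) {
    idx <- build_path_index(g)
    eo <- step_end_offsets(idx, rep(1, idx$path_steps[1]),
                           seq_len(idx$path_steps[1]) - 1L)
    expect_equal(abs(eo[, "start"] - eo[, "end"]),
                 idx$step_len[idx$ptr[1]:(idx$ptr[2] - 1L)])
  }
})

test_that("global step sampling is uniform", {
  idx <- build_path_index(graph_352())
  # single-step graph: only outcome
  g1 <- make_linear(1, seed = 23)
  i1 <- build_path_index(g1)
  s <- sample_global_step(i1, 10)
  expect_true(all(s$rank == 0 & s$path == 1))

  # 5-step index over two paths (2 + 3 steps)
  g <- variation_graph(
    nodes = data.frame(id = 1:3, sequence = c("AC", "G", "TT")),
    edges = data.frame(from = c(1, 2, 1), from_rev = FALSE,
                       to = c(2, 3, 3), to_rev = FALSE),
    paths = list(list(name = "a", node_id = c(1L, 2L), is_reverse = c(FALSE, FALSE)),
                 list(name = "b", node_id = c(1L, 2L, 3L), is_reverse = rep(FALSE, 3))))
  idx5 <- build_path_index(g)
  set.seed(101)
  s <- sample_global_step(idx5, 1e5)
  freq <- tabulate(s$flat, 5) / 1e5
  expect_true(all(abs(freq - 0.2) < 0.01))
  expect_lt(abs(mean(s$path == 2) - 3 / 5), 0.01)

  # chi-square goodness of fit vs uniform on a <=100-step fixture
  gl <- make_linear(80, seed = 24)
  il <- build_path_index(gl)
  set.seed(102)
  s <- sample_global_step(il, 1e5)
  pval <- stats::chisq.test(tabulate(s$flat, 80))$p.value
  expect_gt(pval, 0.001)
})

test_that("sampling is reproducible bit-exactly under a fixed seed", {
  idx <- build_path_index(make_linear(30, seed = 25))
  set.seed(7); a <- sample_global_step(idx, 1000)
  set.seed(7); b <- sample_global_step(idx, 1000)
  expect_identical(a, b)
})
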