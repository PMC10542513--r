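test_that("eta_schedule hits its endpoints and geometric midpoint", {
  expect_equal(eta_schedule(100, 0.01, 31, 0), 100)
  expect_equal(eta_schedule(100, 0.01, 31, 30), 0.01)
  expect_equal(eta_schedule(100, 0.01, 31, 15), sqrt(100 * 0.01))
  expect_equal(eta_schedule(5, 5, 1, 0), 5)  # iter_max = 1
  expect_error(eta_schedule(100, 0.01, 31, 31), "out of range")
  expect_error(eta_schedule(0.01, 100, 31, 0))
})

test_that("2D term update follows the worked example and caps mu", {
  layout <- structure(matrix(c(0, 0, 10, 0,   # X: A, n1 end, B, n2 end
                               0, 0, 0, 0), ncol = 2),
                      frozen = c(FALSE, FALSE), class = "layout_2d")
  term <- manual_term(1L, "start", 2L, "start", nd = 4)

  # eta = 16: mu = 16/16 = 1, r = (10-4)/2 = 3
  res <- apply_term_update_2d(layout, term, eta = 16)
  expect_equal(res$r, 3)
  expect_equal(res$layout[1, ], c(3, 0))
  expect_equal(res$layout[3, ], c(7, 0))
  expect_equal(sqrt(sum((res$layout[3, ] - res$layout[1, ])^2)), 4)

  # eta = 32: eta*w = 2 capped to mu = 1, same displacement
  res2 <- apply_term_update_2d(layout, term, eta = 32)
  expect_equal(res2$r, 3)
  expect_equal(res2$layout[1, ], c(3, 0))

  # ld = nd: fixed point
  layout[3, 1] <- 4
  res3 <- apply_term_update_2d(layout, term, eta = 16)
  expect_equal(res3$r, 0)
  expect_equal(unclass(res3$layout), unclass(layout))
})

test_that("1D term update follows the formula and repels coincident nodes", {
  layout <- structure(c(0, 10), frozen = c(FALSE, FALSE), class = "layout_1d")
  term <- manual_term(1L, "start", 2L, "start", nd = 4)
  res <- apply_term_update_1d(layout, term, eta = 16)
  expect_equal(as.numeric(res$layout), c(3, 7))

  # coincident nodes with nd > 0 are repelled symmetrically by mu*nd/2
  layout2 <- structure(c(5, 5), frozen = c(FALSE, FALSE), class = "layout_1d")
  set.seed(41)
  res2 <- apply_term_update_1d(layout2, term, eta = 16)
  expect_equal(abs(res2$r), 2)  # mu=1, r = (0-4)/2 = -2
  expect_equal(abs(diff(as.numeric(res2$layout))), 4)

  # a same-node term is a no-op in 1D
  same <- manual_term(1L, "start", 1L, "end", nd = 4, rank_a = 0L, rank_b = 0L)
  res3 <- apply_term_update_1d(layout, same, eta = 16)
  expect_equal(res3$r, 0)
  expect_equal(as.numeric(res3$layout), c(0, 10))
})

test_that("a term update never overshoots (contraction property)", {
  set.seed(42)
  overshoot <- vapply(1:10000, function(i) {
    layout <- structure(matrix(rnorm(8, sd = 20), ncol = 2),
                        frozen = c(FALSE, FALSE), class = "layout_2d")
    nd <- sample(0:50, 1)
    ends <- c("start", "end")
    term <- manual_term(1L, sample(ends, 1), 2L, sample(ends, 1), nd = nd)
    i0 <- 2L * (term$node_a - 1L) + ifelse(term$end_a == "start", 1L, 2L)
    j0 <- 2L * (term$node_b - 1L) + ifelse(term$end_b == "start", 1L, 2L)
    ld_old <- sqrt(sum((layout[j0, ] - layout[i0, ])^2))
    res <- apply_term_update_2d(layout, term, eta = runif(1, 0, 1000))
    ld_new <- sqrt(sum((res$layout[j0, ] - res$layout[i0, ])^2))
    abs(ld_new - nd) - abs(ld_old - nd)
  }, numeric(1))
  expect_lte(max(overshoot), 1e-9)
})

test_that("1D initialization lays nodes at prefix-sum offsets", {
  g1 <- make_linear(1, node_len = 5L, seed = 43)
  expect_equal(as.numeric(init_layout_1d(g1)), 0)

  g <- graph_352()
  expect_equal(as.numeric(init_layout_1d(g, "input_order")), c(0, 3, 8))

  set.seed(5); a <- init_layout_1d(g, "random")
  set.seed(5); b <- init_layout_1d(g, "random")
  expect_identical(a, b)
  expect_setequal(as.numeric(a), c(0, 3, 8))
})

test_that("2D initializations: noise, Hilbert origin and locality, path_fixed", {
  g <- graph_352()
  set.seed(44)
  l0 <- init_layout_2d(g, "order_uniform", sigma = 0)
  expect_equal(unname(l0[, "Y"]), rep(0, 6))
  expect_equal(unname(l0[, "X"]), c(0, 3, 3, 8, 8, 10))

  lh <- init_layout_2d(g, "hilbert")
  expect_equal(unname(lh[1, ]), c(0, 0))  # curve origin

  # the curve itself is continuous: consecutive cells are grid neighbors
  for (ord in 1:4) {
    xy <- hilbert_d2xy(ord, 0:(4^ord - 1))
    gaps <- abs(diff(xy[, 1])) + abs(diff(xy[, 2]))
    expect_true(all(gaps == 1))
  }

  expect_error(init_layout_2d(g, "path_fixed", path = "nope"), "unknown path")
  lf <- init_layout_2d(g, "path_fixed", path = "p")
  expect_true(all(attr(lf, "frozen")))
  expect_equal(unname(lf[, "X"]), c(0, 3, 3, 8, 8, 10))
})

test_that("run_pgsgd with zero term updates returns the initialization", {
  g <- graph_352()
  set.seed(45)
  init <- init_layout_2d(g, "order_gaussian")
  out <- run_pgsgd(g, config = sgd_config(iter_max = 1, min_term_updates = 0,
                                          seed = 45),
                   dims = 2, layout = init)
  expect_equal(unclass(out)[, ], unclass(init)[, ], ignore_attr = TRUE)
})

test_that("exact-fit fixture converges: layout distances reach nd", {
  g <- variation_graph(
    nodes = data.frame(id = 1:2, sequence = c("ACG", "TTTTT")),
    edges = data.frame(from = 1, from_rev = FALSE, to = 2, to_rev = FALSE),
    paths = list(list(name = "p", node_id = 1:2, is_reverse = c(FALSE, FALSE))))
  idx <- build_path_index(g)
  lay <- run_pgsgd(g, idx, sgd_config(iter_max = 30, seed = 46), dims = 2)
  terms <- pathsgd:::all_step_pair_terms(idx, 1L)
  for (k in seq_along(terms$nd)) {
    i <- 2L * (terms$node_a[k] - 1L) + ifelse(terms$end_a[k] == "start", 1L, 2L)
    j <- 2L * (terms$node_b[k] - 1L) + ifelse(terms$end_b[k] == "start", 1L, 2L)
    ld <- sqrt(sum((lay[j, ] - lay[i, ])^2))
    expect_lt(abs(ld - terms$nd[k]), 1e-6)
  }
})

test_that("1D run recovers the path order of a shuffled linear graph", {
  g <- shuffle_ids(make_linear(100, seed = 47), seed = 48)
  lay <- run_pgsgd(g, config = sgd_config(seed = 49), dims = 1)
  expect_gte(order_recovery(lay, g, "p"), 0.99)
})

test_that("single-threaded runs are bit-reproducible; translation is preserved", {
  g <- make_linear(40, seed = 50)
  set.seed(51)
  init <- init_layout_2d(g, "order_gaussian")
  a <- run_pgsgd(g, config = sgd_config(iter_max = 10, seed = 52), dims = 2,
                 layout = init)
  b <- run_pgsgd(g, config = sgd_config(iter_max = 10, seed = 52), dims = 2,
                 layout = init)
  expect_identical(as.numeric(a), as.numeric(b))

  shifted <- init
  shifted[, 1] <- shifted[, 1] + 1000
  shifted[, 2] <- shifted[, 2] - 500
  c2 <- run_pgsgd(g, config = sgd_config(iter_max = 10, seed = 52), dims = 2,
                  layout = shifted)
  expect_equal(c2[, 1] - 1000, a[, 1], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(c2[, 2] + 500, a[, 2], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("frozen nodes never move", {
  g <- make_snp_bubbles(20, 0.5, 2, seed = 53)
  set.seed(54)
  init <- init_layout_2d(g, "path_fixed", path = "p1")
  lay <- run_pgsgd(g, config = sgd_config(iter_max = 20, seed = 54), dims = 2,
                   layout = init)
  frozen_rows <- rep(attr(init, "frozen"), each = 2)
  expect_identical(unclass(lay)[frozen_rows, ], unclass(init)[frozen_rows, ])
  expect_false(identical(unclass(lay)[!frozen_rows, ], unclass(init)[!frozen_rows, ]))
})

test_that("the per-iteration callback sees the schedule and can stop the run", {
  g <- make_linear(20, seed = 55)
  log <- list()
  lay <- run_pgsgd(g, config = sgd_config(iter_max = 10, seed = 56), dims = 2,
                   callback = function(t, eta, max_r) {
                     log[[length(log) + 1]] <<- c(t, eta, max_r)
                     t < 3  # stop after the 4th iteration
                   })
  expect_length(log, 4L)
  sched <- attr(lay, "schedule")
  expect_equal(sched$iter, 0:3)
  expect_equal(sched$eta, eta_schedule(max(build_path_index(g)$path_len)^2,
                                       0.01, 10, 0:3))
})
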