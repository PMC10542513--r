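test_that("zipf_sample matches the analytic law", {
  # N=1: single outcome
  expect_true(all(zipf_sample(100, zipf_spec(1, 1L)) == 1L))

  # N=2, theta=1: P(1)=2/3, P(2)=1/3 (H = 1.5)
  set.seed(31)
  k <- zipf_sample(1e5, zipf_spec(1, 2L))
  expect_lt(abs(mean(k == 1) - 2 / 3), 0.01)
  expect_lt(abs(mean(k == 2) - 1 / 3), 0.01)

  # N=100, theta=0.99: empirical CDF within 0.005 of the analytic CDF
  spec <- zipf_spec(0.99, 100L)
  set.seed(32)
  k <- zipf_sample(1e5, spec)
  emp <- cumsum(tabulate(k, 100)) / 1e5
  expect_lt(max(abs(emp - cumsum(zipf_probs(spec)))), 0.005)
})

test_that("zipf_probs sums to one and is proportional to k^-theta", {
  p <- zipf_probs(zipf_spec(1.5, 50L))
  expect_equal(sum(p), 1)
  expect_equal(p[2] / p[1], 2^-1.5)
})

test_that("sample_partner honors boundaries and the two-sided law", {
  idx2 <- build_path_index(parse_gfa(tiny_gfa))
  # 2-step path in zipf mode: always the other step
  expect_true(all(sample_partner(idx2, 1, 0, "zipf", zipf_spec(), n = 200) == 1L))
  expect_true(all(sample_partner(idx2, 1, 1, "zipf", zipf_spec(), n = 200) == 0L))

  # at rank 0 the negative direction is always flipped to positive
  idx10 <- build_path_index(make_linear(10, seed = 33))
  set.seed(33)
  p <- sample_partner(idx10, 1, 0, "zipf", zipf_spec(1.5, 9L), n = 2000)
  expect_true(all(p >= 1L & p <= 9L))

  # two-sided law from rank 50 of a 100-step path, theta=2:
  # enumeration oracle over (k, direction) with the flip/clamp rule
  idx100 <- build_path_index(make_linear(100, seed = 34))
  spec <- zipf_spec(2, 10000L)
  m <- 100L; ra <- 50L
  w <- min(spec$window, m - 1L)
  pk <- zipf_probs(zipf_spec(2, w))
  expected <- numeric(m)  # P(partner rank)
  for (k in seq_len(w)) {
    for (d in c(-1L, 1L)) {
      t <- ra + d * k
      if (t < 0L || t > m - 1L) t <- ra - d * k
      if (t < 0L) t <- 0L
      if (t > m - 1L) t <- m - 1L
      expected[t + 1L] <- expected[t + 1L] + pk[k] / 2
    }
  }
  set.seed(34)
  p <- sample_partner(idx100, 1, ra, "zipf", spec, n = 1e5)
  emp <- tabulate(p + 1L, m) / 1e5
  expect_lt(max(abs(emp - expected)), 0.01)

  # uniform mode covers the whole path uniformly
  set.seed(35)
  u <- sample_partner(idx10, 1, 4, "uniform", n = 5e4)
  expect_true(all(abs(tabulate(u + 1L, 10) / 5e4 - 0.1) < 0.01))
})

test_that("terms on a 1-step path join the node's two ends with nd = length", {
  g <- make_linear(1, node_len = 7L, seed = 36)
  idx <- build_path_index(g)
  set.seed(36)
  t <- sample_term(idx, sampler_config())
  expect_equal(t$node_a, t$node_b)
  expect_setequal(c(t$end_a, t$end_b), c("start", "end"))
  expect_equal(t$nd, 7)
})

test_that("adjacent node ends coincide in path space (nd = 0)", {
  g <- variation_graph(
    nodes = data.frame(id = 1:2, sequence = c("ACG", "TTTTT")),
    edges = data.frame(from = 1, from_rev = FALSE, to = 2, to_rev = FALSE),
    paths = list(list(name = "p", node_id = 1:2, is_reverse = c(FALSE, FALSE))))
  idx <- build_path_index(g)
  t <- pathsgd:::term_from_steps(idx, 1L, 0L, 1L)
  expect_equal(t$end_a, "end")    # node 1's sequence-end end, at offset 3
  expect_equal(t$end_b, "start")  # node 2's sequence-start end, at offset 3
  expect_equal(t$nd, 0)
})

test_that("nd equals the brute-force offset difference for sampled terms", {
  g <- fixture_graphs()$inv
  idx <- build_path_index(g)
  set.seed(37)
  for (i in 1:200) {
    t <- sample_term(idx, sampler_config(), progress = runif(1))
    eo_a <- step_end_offsets(idx, t$path, t$rank_a)
    eo_b <- step_end_offsets(idx, t$path, t$rank_b)
    expect_true(t$pos_a %in% eo_a)
    expect_true(t$pos_b %in% eo_b)
    expect_equal(t$nd, abs(t$pos_a - t$pos_b))
    # never pairs steps from different paths
    expect_lt(t$rank_a, idx$path_steps[t$path])
    expect_lt(t$rank_b, idx$path_steps[t$path])
  }
})

test_that("flip draws uniform mode in half of the updates", {
  idx <- build_path_index(make_linear(100, seed = 38))
  set.seed(38)
  modes <- replicate(1e4, sample_term(idx, sampler_config())$mode)
  expect_lt(abs(mean(modes == "uniform") - 0.5), 0.02)
})

test_that("cooling strictly lowers the mean nd of zipf-mode terms", {
  idx <- build_path_index(make_linear(100, seed = 39))
  cfg <- sampler_config(flip_probability = 0)  # zipf-mode terms only
  set.seed(39)
  nd_warm <- replicate(1e4, sample_term(idx, cfg, progress = 0)$nd)
  set.seed(39)
  nd_cool <- replicate(1e4, sample_term(idx, cfg, progress = 0.9)$nd)
  expect_lt(mean(nd_cool), mean(nd_warm))
})

test_that("sampler_config validates its fields", {
  expect_error(sampler_config(flip_probability = 1.5))
  expect_error(zipf_spec(theta = 0))
  expect_error(zipf_spec(window = 0))
})
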