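test_that("normalize_profiles returns row-stochastic observed profiles", {
  panel <- toy_panel(rbind(c(5L, 0L, 5L), c(1L, 2L, 3L)), c(2L, 2L, 2L))
  g <- normalize_profiles(panel$problem)
  expect_equal(g[1, ], c(t1 = 0.5, t2 = 0, t3 = 0.5))
  expect_equal(unname(rowSums(g)), rep(1, 2), tolerance = 1e-9)

  one <- toy_panel(matrix(7L, 1, 1), 3L)
  expect_equal(unname(normalize_profiles(one$problem)), matrix(1, 1, 1))
})

test_that("screening recovers an exactly representable sink and zeroes under heavy penalty", {
  set.seed(42)
  g1 <- rlnorm(40, 0, 1); g1 <- g1 / sum(g1)
  g2 <- rlnorm(40, 0, 1); g2 <- g2 / sum(g2)
  gam <- rbind(g1, g2)
  sel <- solve_sparse_qp(g1, gam, 1e-6)
  expect_equal(unname(sel$alpha_init), c(1, 0), tolerance = 1e-4)

  sel0 <- solve_sparse_qp(g1, gam, 10)
  expect_equal(unname(sel0$alpha_init), c(0, 0))
  expect_length(sel0$support, 0)

  # zero is always feasible, so the returned objective can never exceed it
  expect_lte(sel$objective, sum(g1^2) + 1e-12)
})

test_that("single-source screening matches the closed-form clipped projection", {
  # with lam = 0 and one source the optimum is <g,x>/<g,g> clipped to [0,1]
  for (seed in 1:5) {
    set.seed(seed)
    g <- rlnorm(30, 0, 2); g <- g / sum(g)
    x <- rlnorm(30, 0, 2); x <- x / sum(x)
    expected <- min(1, max(0, sum(g * x) / sum(g * g)))
    sel <- solve_sparse_qp(x, matrix(g, nrow = 1), 0)
    expect_equal(sel$alpha_init, expected, tolerance = 1e-8)
  }
})

test_that("screening support shrinks monotonically along a penalty ladder", {
  panel <- random_problem(M = 8, N = 60, depth = 4000, k = 3, seed = 9)
  pr <- panel$problem
  gam <- normalize_profiles(pr)
  xr <- as.numeric(pr$sink) / pr$sink_total
  ladder <- c(1e-8, 1e-6, 1e-4, 1e-2, 1e-1, 1)
  sizes <- vapply(ladder, function(l) {
    length(solve_sparse_qp(xr, gam, l)$support)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[length(sizes)], 0)
})

test_that("non-finite screening inputs are rejected", {
  expect_error(solve_sparse_qp(c(NA, 1), matrix(0.5, 1, 2), 0), "non-finite")
  expect_error(solve_sparse_qp(c(0.5, 0.5), matrix(0.5, 1, 2), -1), "nonnegative")
})

test_that("unknown profile is the clipped residual and never exceeds the sink", {
  panel <- toy_panel(rbind(c(8L, 0L, 4L), c(1L, 1L, 1L)), c(10L, 5L, 0L))
  sel <- structure(list(alpha_init = c(0.5, 0)), class = "selection_result")

  # printed top-source variant on the worked example
  unk_top <- init_unknown_profile(panel$problem, sel, subtract = "top")
  expect_equal(unk_top$counts, c(6, 5, 0))
  expect_equal(unk_top$total, 11)

  # with a single selected source both variants coincide
  unk_sel <- init_unknown_profile(panel$problem, sel)
  expect_equal(unk_sel$counts, unk_top$counts)

  # nothing selected: the whole sink goes to the unknown
  sel0 <- structure(list(alpha_init = c(0, 0)), class = "selection_result")
  expect_equal(init_unknown_profile(panel$problem, sel0)$counts, c(10, 5, 0))

  # exact cancellation gives the zero vector
  panel2 <- toy_panel(matrix(c(20L, 10L, 2L), 1), c(10L, 5L, 1L))
  sel2 <- structure(list(alpha_init = 0.5), class = "selection_result")
  expect_equal(init_unknown_profile(panel2$problem, sel2)$counts, c(0, 0, 0))

  # clipping bounds the profile by the sink counts elementwise
  for (seed in 1:5) {
    p <- random_problem(M = 4, N = 30, seed = seed)
    gam <- normalize_profiles(p$problem)
    xr <- as.numeric(p$problem$sink) / p$problem$sink_total
    sel <- solve_sparse_qp(xr, gam, 1e-6)
    unk <- init_unknown_profile(p$problem, sel)
    expect_true(all(unk$counts <= as.numeric(p$problem$sink) + 1e-9))
    expect_true(all(unk$counts >= 0))
  }
})

test_that("cross-validation returns the singleton grid and prefers sparser ties", {
  probs <- lapply(1:4, function(s) random_problem(M = 6, N = 50, seed = s)$problem)
  expect_equal(cross_validate_lambda(probs, 1e-6, split_seed = 1), 1e-6)
  expect_error(cross_validate_lambda(probs, numeric(0)), "empty")
  expect_error(cross_validate_lambda(probs, c(1e-4, 1e-6)), "increasing")
  expect_error(cross_validate_lambda(probs[1], 1e-6), "at least 2")

  lam <- cross_validate_lambda(probs, c(1e-6, 1e-4, 1e-2, 1e-1), split_seed = 3)
  expect_true(lam %in% c(1e-6, 1e-4))
})

test_that("held-out prediction error is non-decreasing in the over-penalized regime", {
  cfg <- simulation_config(n_taxa = 150, n_candidates = 10, n_contributing = 3,
                           n_sinks = 4, unknown_prop = 0, seed = 21)
  ds <- build_dataset(cfg)
  grid <- c(1e-2, 5e-2, 1e-1, 5e-1)
  eps <- vapply(grid, function(l) {
    mean(vapply(ds$problems, function(pr) {
      sel <- solve_sparse_qp(as.numeric(pr$sink) / pr$sink_total,
                             normalize_profiles(pr), l)
      mean(sel$residual^2)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(eps) >= -1e-12))
})
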