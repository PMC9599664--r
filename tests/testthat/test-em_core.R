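test_that("responsibilities follow the posterior formula and normalize", {
  # disjoint supports: each taxon is claimed entirely by its own source
  p <- e_step(c(0.5, 0.5), rbind(c(1, 0), c(0, 1)), c(3, 3))
  expect_equal(p, rbind(c(1, 0), c(0, 1)))

  # direct evaluation: p(1|1) = 0.6*0.5 / (0.6*0.5 + 0.4*0.25) = 0.75
  p2 <- e_step(c(0.6, 0.4), rbind(c(0.5, 0.5), c(0.25, 0.75)), c(1, 1))
  expect_equal(p2[1, 1], 0.3 / 0.4)

  for (seed in 1:10) {
    set.seed(seed)
    M1 <- sample(2:6, 1)
    N <- sample(3:20, 1)
    a <- rexp(M1); a <- a / sum(a)
    g <- matrix(rexp(M1 * N), M1); g <- g / rowSums(g)
    p <- e_step(a, g, rep(1, N))
    expect_equal(unname(colSums(p)), rep(1, N), tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
  }

  # dead columns become uniform over sources with positive mixing weight
  pd <- e_step(c(0.5, 0.5, 0), rbind(c(1, 0), c(1, 0), c(1, 0)), c(2, 1))
  expect_equal(pd[, 2], c(0.5, 0.5, 0))
})

test_that("profile M-step blends sink responsibilities with observed counts", {
  # y = (5,5), x = (10,10), p(i|.) = (1,0): gamma = (15, 5+... )
  resp <- rbind(c(1, 0), c(0, 1))
  Y <- rbind(c(5, 5), c(5, 5))
  g <- m_step_gamma(resp, c(10, 10), Y)
  expect_equal(g[1, ], c(15 / 20, 5 / 20))

  # zero responsibilities reduce to the observed profile
  g0 <- m_step_gamma(matrix(0, 2, 2), c(10, 10), Y)
  expect_equal(g0, Y / rowSums(Y))

  for (seed in 1:10) {
    set.seed(seed)
    M1 <- sample(2:5, 1); N <- sample(3:15, 1)
    resp <- matrix(runif(M1 * N), M1); resp <- sweep(resp, 2, colSums(resp), "/")
    Y <- matrix(rpois(M1 * N, 4), M1)
    g <- m_step_gamma(resp, rpois(N, 6), Y + 1)
    expect_equal(unname(rowSums(g)), rep(1, M1), tolerance = 1e-9)
  }
})

test_that("mixing M-step solves the penalized simplex problem exactly", {
  # lam = 0 closed form c / sum(c)
  resp <- rbind(c(1, 0.5), c(0, 0.5))
  a <- m_step_alpha(rbind(c(0.75, 0.75), c(0.25, 0.25)), c(2, 2), 0)
  expect_equal(a, c(0.75, 0.25))

  # frozen oracle: maximize 3 log a1 + log a2 - a1 on the simplex
  # (1-D numeric maximization gives 0.6972244)
  a2 <- m_step_alpha(rbind(rep(0.75, 2), rep(0.25, 2)), c(2, 2), 1)
  expect_equal(a2, c(0.6972244, 0.3027756), tolerance = 1e-6)

  # zero-responsibility sources are exactly zero
  resp3 <- rbind(c(0.7, 0.7), c(0, 0), c(0.3, 0.3))
  a3 <- m_step_alpha(resp3, c(5, 5), 0.5)
  expect_identical(a3[2], 0)
  expect_equal(sum(a3), 1, tolerance = 1e-9)

  expect_error(m_step_alpha(matrix(0, 2, 2), c(1, 1), 1), "empty sink")
})

test_that("mixing M-step matches the grid-refinement oracle across random draws", {
  set.seed(100)
  for (rep in 1:12) {
    M <- sample(2:4, 1)
    cvec <- rexp(M + 1) * 10
    lam <- runif(1, 0, 5)
    resp <- cbind(cvec, cvec) / 2   # two identical columns, x = (1,1)
    got <- m_step_alpha(resp, c(1, 1), lam)
    want <- grid_maximize_alpha_objective(cvec, lam)
    expect_equal(got, want, tolerance = 1.5e-3)
  }
})

test_that("likelihood matches an independent term-by-term summation", {
  set.seed(8)
  M1 <- 3; N <- 6
  a <- c(0.5, 0.3, 0.2)
  g <- matrix(rexp(M1 * N), M1); g <- g / rowSums(g)
  x <- rpois(N, 10)
  Y <- matrix(rpois(M1 * N, 5), M1)
  lam <- 0.7
  out <- penalized_log_likelihood(a, g, lam, x, Y)

  ll <- 0
  for (j in seq_len(N)) {
    ll <- ll + x[j] * log(sum(a * g[, j]))
    for (i in seq_len(M1)) if (Y[i, j] > 0) ll <- ll + Y[i, j] * log(g[i, j])
  }
  expect_equal(out$loglik, ll, tolerance = 1e-10)
  expect_equal(out$penalized_obj, ll - lam * sum(a[1:2]) + 2 * log(lam),
               tolerance = 1e-10)

  # plug-in check: single source carrying the whole sink
  gx <- matrix(c(x / sum(x), rep(1 / N, N)), 2, byrow = TRUE)
  out2 <- penalized_log_likelihood(c(1, 0), gx, 0, x,
                                   rbind(Y[1, ], rep(0, N)))
  expect_equal(out2$loglik,
               sum(x * log(x / sum(x))) + sum(Y[1, ] * log(x / sum(x))),
               tolerance = 1e-10)
})

test_that("EM ascends its penalized objective on random problems", {
  for (seed in 1:20) {
    panel <- random_problem(M = sample(2:6, 1), N = sample(20:50, 1),
                            depth = 1000, seed = seed)
    pr <- panel$problem
    gam <- normalize_profiles(pr)
    sel <- solve_sparse_qp(as.numeric(pr$sink) / pr$sink_total, gam, 1e-6)
    init <- list(alpha_init = sel$alpha_init, gamma_init = gam,
                 unknown = init_unknown_profile(pr, sel))
    st <- run_em(pr, 10^runif(1, -8, -2), init, tol = 1e-8, max_iter = 200)
    expect_true(all(diff(st$obj_trace) >= -1e-10))
    expect_equal(sum(st$alpha), 1, tolerance = 1e-9)
    expect_equal(unname(rowSums(st$gamma)), rep(1, nrow(st$gamma)),
                 tolerance = 1e-9)
  }
})

test_that("one unpenalized pass with fixed profiles is the classical mixture update", {
  panel <- random_problem(M = 3, N = 25, seed = 4)
  pr <- panel$problem
  gam <- normalize_profiles(pr)
  x <- as.numeric(pr$sink)
  alpha0 <- c(0.3, 0.3, 0.2, 0.2)
  gamma0 <- rbind(gam, rep(1 / ncol(gam), ncol(gam)))
  resp <- e_step(alpha0, gamma0, x)
  a_new <- m_step_alpha(resp, x, 0)
  cvec <- drop(resp %*% x)
  expect_equal(a_new, cvec / sum(cvec), tolerance = 1e-12)
})

test_that("EM recovers a single-source sink and flags convergence", {
  set.seed(77)
  N <- 150
  prof <- t(sapply(1:2, function(i) { w <- rlnorm(N, 0, 2); w / sum(w) }))
  Y <- t(apply(prof, 1, function(p) drop(rmultinom(1, 20000, p))))
  x <- drop(rmultinom(1, 100000, prof[1, ]))
  keep <- x > 0 | colSums(Y) > 0
  panel <- toy_panel(Y[, keep], x[keep])
  st <- track_sink(panel$problem)
  expect_gte(st$alpha[["src1"]], 0.99)
  expect_lte(st$alpha[["Unknown"]], 0.01)
  expect_true(st$converged)
})

test_that("grid search honors its argmax contract", {
  panel <- random_problem(M = 6, N = 60, depth = 3000, k = 2, seed = 31)
  pr <- panel$problem
  gam <- normalize_profiles(pr)
  sel <- solve_sparse_qp(as.numeric(pr$sink) / pr$sink_total, gam, 1e-6)
  init <- list(alpha_init = sel$alpha_init, gamma_init = gam,
               unknown = init_unknown_profile(pr, sel))

  single <- grid_search(pr, 1e-6, init)
  direct <- run_em(pr, 1e-6, init)
  expect_equal(single$alpha, direct$alpha, tolerance = 1e-12)

  st <- grid_search(pr, default_lambda_grid(), init)
  grid <- attr(st, "grid")
  expect_equal(nrow(grid), 7)
  expect_true(all(st$loglik >= grid$loglik - 1e-9))
  # support at the returned state is contained in the least-penalized support
  small <- run_em(pr, 1e-8, init)
  expect_true(all(which(st$alpha[-length(st$alpha)] > 1e-8) %in%
                  which(small$alpha[-length(small$alpha)] > 1e-8) |
                  length(which(st$alpha[-length(st$alpha)] > 1e-8)) == 0))

  expect_error(grid_search(pr, numeric(0), init), "empty")
  expect_error(grid_search(pr, c(1e-4, 1e-6), init), "increasing")
})
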