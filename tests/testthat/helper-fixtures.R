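# Shared fixtures and independent brute-force oracles.

# Small in-memory count table + metadata for a single-sink problem.
toy_panel <- function(Y, x, taxa = NULL) {
  M <- nrow(Y)
  N <- ncol(Y)
  taxa <- taxa %||% paste0("t", seq_len(N))
  ids <- c(paste0("src", seq_len(M)), "sink1")
  ct <- count_table(t(rbind(Y, x)), taxa_ids = taxa, sample_ids = ids)
  md <- data.frame(SampleID = ids, Env = "env",
                   SourceSink = c(rep("Source", M), "Sink"),
                   id = NA_character_)
  list(counts = ct, metadata = md,
       problem = build_problem(ct, md, "sink1"))
}

# Random single-sink problem: M sources with log-normal profiles, the sink a
# multinomial mixture of a few of them plus optional unseen mass.
random_problem <- function(M, N, depth = 2000, k = min(3, M),
                           unknown = 0, seed = 1) {
  set.seed(seed)
  prof <- t(sapply(seq_len(M + 1), function(i) {
    w <- rlnorm(N, 0, 2)
    w / sum(w)
  }))
  Y <- t(apply(prof[seq_len(M), , drop = FALSE], 1,
               function(p) drop(rmultinom(1, depth, p))))
  contrib <- sample(M, k)
  a <- c(rep(0, M), unknown)
  a[contrib] <- (1 - unknown) * {
    w <- rexp(k)
    w / sum(w)
  }
  beta <- drop(crossprod(prof, a))
  x <- drop(rmultinom(1, depth, beta))
  keep <- x > 0 | colSums(Y) > 0
  panel <- toy_panel(Y[, keep, drop = FALSE], x[keep])
  panel$true_alpha <- a
  panel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive grid over {a >= 0, sum(a) <= slack_total} at a fixed step.
# fn takes a P x M matrix of candidate points and returns a vector of values.
full_simplex_grid <- function(M, step, lower = rep(0, M), upper = rep(1, M),
                              slack_total = 1) {
  axes <- lapply(seq_len(M), function(i) {
    v <- seq(max(0, lower[i]), min(1, upper[i]), by = step)
    unique(pmin(pmax(v, 0), 1))
  })
  pts <- unname(as.matrix(expand.grid(axes)))
  pts[rowSums(pts) <= slack_total + 1e-12, , drop = FALSE]
}

# Coarse-to-fine exhaustive minimization over {a >= 0, sum(a) <= 1}; valid as
# a global oracle for convex objectives (each refinement brackets the optimum).
grid_opt_subsimplex <- function(fn, M, steps = c(0.02, 0.005, 0.001),
                                maximize = FALSE) {
  sgn <- if (maximize) -1 else 1
  lower <- rep(0, M)
  upper <- rep(1, M)
  best <- NULL
  for (s in steps) {
    pts <- full_simplex_grid(M, s, lower, upper)
    vals <- sgn * fn(pts)
    best <- unname(pts[which.min(vals), ])
    lower <- best - 2.5 * s
    upper <- best + 2.5 * s
  }
  best
}

# Oracle for the EM alpha step: maximize sum(c_i log a_i) - lam * sum(a[1:M])
# over the full simplex sum(a) = 1 (the last coordinate is the unknown),
# by exhaustive refinement over the first M coordinates.
grid_maximize_alpha_objective <- function(cvec, lam,
                                          steps = c(0.05, 0.01, 0.002, 5e-4, 1e-4)) {
  Mp1 <- length(cvec)
  M <- Mp1 - 1L
  fn <- function(pts) {
    last <- pmax(1 - rowSums(pts), 0)
    full <- cbind(pts, last)
    vals <- rowSums(sweep(log(pmax(full, 1e-300)), 2, cvec, "*"))
    vals - lam * rowSums(pts)
  }
  a_known <- grid_opt_subsimplex(fn, M, steps, maximize = TRUE)
  c(a_known, 1 - sum(a_known))
}

# Evaluate an expression under a temporary seed (lazy promise forces after set.seed).
local_seed_draw <- function(seed, expr) {
  set.seed(seed)
  expr
}
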