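#' Observed relative-abundance profiles of the candidate sources
#'
#' Normalizes each source's count vector by its total, giving the row-stochastic
#' matrix used both as the design matrix of the selection step and as the
#' initial latent profiles for EM.
#'
#' @param problem A [build_problem()] result.
#' @return M x N matrix with rows summing to 1.
#' @export
normalize_profiles <- function(problem) {
  if (any(problem$source_totals <= 0)) st_stop("source with zero total reads")
  sweep(unclass(problem$sources), 1, problem$source_totals, "/")
}

# Euclidean projection onto {a >= 0, sum(a) <= 1}: clip to the orthant and,
# only if the clipped point overshoots the budget, project onto the simplex.
project_subsimplex <- function(a) {
  p <- pmax(a, 0)
  s <- sum(p)
  if (s <= 1) return(p)
  u <- sort(a, decreasing = TRUE)
  css <- cumsum(u) - 1
  rho <- max(which(u - css / seq_along(u) > 0))
  pmax(a - css[rho] / rho, 0)
}

#' L1-penalized simplex-constrained least squares for source screening
#'
#' Solves
#' \deqn{\hat\alpha = \arg\min_\alpha \|\Gamma^\top \alpha - x\|_2^2 +
#'   \lambda \|\alpha\|_1 \quad \text{s.t. } \alpha \ge 0,\ \sum_i \alpha_i \le 1}
#' where the rows of \eqn{\Gamma} are the observed source relative-abundance
#' profiles and \eqn{x} is the sink's relative abundance. Because
#' \eqn{\alpha \ge 0}, the L1 term is the linear term \eqn{\lambda\sum\alpha_i};
#' the problem is a convex QP solved by accelerated projected gradient descent
#' with an exact projection onto the simplex-with-slack.
#'
#' @param x_rel Length-N sink relative abundance (sums to 1).
#' @param gamma_init M x N row-stochastic profile matrix
#'   (from [normalize_profiles()]).
#' @param lam Nonnegative L1 penalty weight.
#' @param support_tol Entries above this count as selected (default `1e-8`).
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Iteration cap; exceeding it is an error, never a silent
#'   partial answer.
#' @return A list of class `selection_result`: `alpha_init` (length M,
#'   nonnegative, sum <= 1), `support` (indices with `alpha_init >
#'   support_tol`), `lambda_used`, `residual` (`x_rel - t(gamma) %*% alpha`),
#'   `objective`, `n_iter`.
#' @export
solve_sparse_qp <- function(x_rel, gamma_init, lam, support_tol = 1e-8,
                            tol = 1e-13, max_iter = 100000L) {
  if (!all(is.finite(x_rel)) || !all(is.finite(gamma_init)) || !is.finite(lam)) {
    st_stop("non-finite inputs to solve_sparse_qp")
  }
  if (lam < 0) st_stop("lam must be nonnegative")
  M <- nrow(gamma_init)
  G <- gamma_init %*% t(gamma_init)          # M x M Gram matrix
  b <- drop(gamma_init %*% x_rel)
  L <- 2 * max(norm(G, "2"), .Machine$double.eps)
  obj <- function(a) {
    drop(a %*% G %*% a) - 2 * sum(b * a) + sum(x_rel^2) + lam * sum(a)
  }
  grad <- function(a) 2 * drop(G %*% a - b) + lam

  alpha <- rep(0, M)
  z <- alpha
  t_k <- 1
  f_prev <- obj(alpha)
  stall <- 0L
  it <- 0L
  for (it in seq_len(max_iter)) {
    alpha_new <- project_subsimplex(z - grad(z) / L)
    f_new <- obj(alpha_new)
    if (f_new > f_prev) {            # monotone restart
      alpha_new <- project_subsimplex(alpha - grad(alpha) / L)
      f_new <- obj(alpha_new)
      t_k <- 1
    }
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- alpha_new + ((t_k - 1) / t_new) * (alpha_new - alpha)
    t_k <- t_new
    rel <- abs(f_prev - f_new) / max(abs(f_prev), 1e-15)
    alpha <- alpha_new
    f_prev <- f_new
    stall <- if (rel < tol) stall + 1L else 0L
    if (stall >= 5L) break
  }
  if (stall < 5L) {
    st_stop("sparse QP did not converge in ", max_iter,
            " iterations (last relative objective change above ", tol, ")")
  }
  alpha[alpha < 0] <- 0
  names(alpha) <- rownames(gamma_init)
  structure(list(
    alpha_init = alpha,
    support = which(alpha > support_tol),
    lambda_used = lam,
    residual = x_rel - drop(t(gamma_init) %*% alpha),
    objective = f_prev,
    n_iter = it
  ), class = "selection_result")
}

#' Choose the selection penalty by cross-validation
#'
#' Splits the sinks into halves by a seeded permutation and, for each candidate
#' penalty, measures the mean per-taxon squared residual
#' \eqn{\epsilon = \mathrm{mean}_j (x_j - (\Gamma^\top\alpha)_j)^2}
#' of the penalized fit on the held-out half. Returns the penalty with the
#' smallest mean error; ties are broken toward the larger (sparser) penalty.
#' Because the selection coefficients are per-sink, the fit at each penalty is
#' recomputed on each held-out sink; the split confines the choice of the
#' penalty to sinks disjoint from the training half.
#'
#' @param problems List of [build_problem()] results (at least 2).
#' @param lambda_grid Strictly increasing positive penalties.
#' @param split_seed Integer seed for the half/half split.
#' @return The chosen penalty (scalar).
#' @export
cross_validate_lambda <- function(problems, lambda_grid, split_seed = 1L) {
  if (length(lambda_grid) == 0) st_stop("empty lambda grid")
  if (any(diff(lambda_grid) <= 0)) st_stop("lambda grid must be strictly increasing")
  if (length(problems) < 2) st_stop("cross-validation needs at least 2 sinks")
  n <- length(problems)
  perm <- local_seed(split_seed, sample.int(n))
  test <- perm[(floor(n / 2) + 1):n]
  eps <- vapply(lambda_grid, function(lam) {
    mean(vapply(test, function(k) {
      pr <- problems[[k]]
      gam <- normalize_profiles(pr)
      sel <- solve_sparse_qp(pr$sink / pr$sink_total, gam, lam)
      mean(sel$residual^2)
    }, numeric(1)))
  }, numeric(1))
  best <- 1L
  for (k in seq_along(lambda_grid)) if (eps[k] <= eps[best]) best <- k
  lambda_grid[[best]]
}

#' Initialize the unknown source's pseudo-count profile
#'
#' The unknown source aggregates all unobserved environments. Its initial
#' pseudo-counts are the nonnegative residual of the sink after removing the
#' prominent signal of the screened known sources. With `subtract =
#' "selected"` (the default) all screened sources are removed,
#' \eqn{\hat Y_{M+1} = \max(0, x - \sum_i \hat\alpha_i Y_i)}, so the residual
#' approximates the unknown source's own contribution; with `subtract = "top"`
#' only the top selected source is removed,
#' \eqn{\hat Y_{M+1} = \max(0, x - \hat\alpha_{i^*} Y_{i^*})} with
#' \eqn{i^* = \arg\max_i \hat\alpha_i} (ties to the lowest index). The top-only
#' residual retains the signatures of the remaining contributing sources, which
#' makes the unknown partially exchangeable with them during EM and biases the
#' unknown proportion upward; see the methods vignette. When the screening
#' selected nothing, the whole sink is handed to the unknown.
#'
#' @param problem The [build_problem()] result the selection was computed on.
#' @param selection A [solve_sparse_qp()] result.
#' @param subtract `"selected"` (all screened sources) or `"top"` (top source
#'   only).
#' @return List with `counts` (length-N nonnegative vector) and `total`.
#' @export
init_unknown_profile <- function(problem, selection,
                                 subtract = c("selected", "top")) {
  subtract <- match.arg(subtract)
  x <- as.numeric(problem$sink)
  a <- selection$alpha_init
  if (length(a) != nrow(problem$sources)) st_stop("selection/problem shape mismatch")
  if (all(a == 0)) {
    counts <- x
  } else if (subtract == "top") {
    i_star <- which.max(a)
    counts <- pmax(0, x - a[i_star] * as.numeric(problem$sources[i_star, ]))
  } else {
    counts <- pmax(0, x - drop(t(unclass(problem$sources)) %*% a))
  }
  list(counts = counts, total = sum(counts))
}
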