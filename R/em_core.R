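#' @keywords internal
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' E-step: read-origin responsibilities
#'
#' Computes the posterior probability that a sink read of taxon j originated
#' from source i under the current mixture:
#' \eqn{p(i|j) = \alpha_i\gamma_{ij} / \sum_{i'}\alpha_{i'}\gamma_{i'j}}.
#' Columns whose mixture mass \eqn{\beta_j = \sum_i \alpha_i\gamma_{ij}} is
#' zero are set to the uniform distribution over sources with positive
#' \eqn{\alpha}; such columns only arise for taxa the mixture cannot explain
#' and carry weight only through the likelihood clamp.
#'
#' @param alpha Length-(M+1) mixing proportions (last entry = unknown).
#' @param gamma (M+1) x N row-stochastic latent profiles.
#' @param x Length-N sink counts (unused by the formula; kept for shape checks).
#' @return (M+1) x N responsibility matrix; every column sums to 1.
#' @export
e_step <- function(alpha, gamma, x) {
  stopifnot(length(alpha) == nrow(gamma), length(x) == ncol(gamma))
  w <- alpha * gamma                 # recycles alpha down columns
  beta <- colSums(w)
  p <- sweep(w, 2, pmax(beta, .Machine$double.xmin), "/")
  dead <- beta == 0
  if (any(dead)) {
    pos <- alpha > 0
    p[, dead] <- 0
    p[pos, dead] <- 1 / sum(pos)
  }
  p
}

#' M-step for the latent profiles
#'
#' \eqn{\gamma_{ij} = (x_j p(i|j) + y_{ij}) / \sum_j (x_j p(i|j) + y_{ij})},
#' applied uniformly to all M+1 rows; row M+1 of `Y` carries the plug-in
#' unknown pseudo-counts.
#'
#' @param resp Responsibilities from [e_step()].
#' @param x Sink counts.
#' @param Y (M+1) x N count matrix (candidate sources plus the unknown row).
#' @return (M+1) x N row-stochastic matrix.
#' @export
m_step_gamma <- function(resp, x, Y) {
  num <- sweep(resp, 2, x, "*") + Y
  tot <- rowSums(num)
  zero <- tot == 0
  if (any(zero)) {                   # cannot occur when all C_i > 0
    num[zero, ] <- 1
    tot[zero] <- ncol(num)
  }
  num / tot
}

#' M-step for the mixing proportions
#'
#' Maximizes \eqn{\sum_{i=1}^{M+1} c_i \log\alpha_i - \lambda\sum_{i\le M}
#' \alpha_i} over the full simplex \eqn{\sum_{i=1}^{M+1}\alpha_i = 1},
#' \eqn{\alpha \ge 0}, where \eqn{c_i = \sum_j x_j p(i|j)}. The stationarity
#' conditions give \eqn{\alpha_i = c_i/(\lambda+\nu)} for known sources and
#' \eqn{\alpha_{M+1} = c_{M+1}/\nu}; the multiplier \eqn{\nu} is found by
#' monotone 1-D root finding on \eqn{\sum_i \alpha_i(\nu) = 1} (bracketed
#' bisection via [stats::uniroot()] followed by Newton polishing). Sources
#' with \eqn{c_i = 0} get exactly zero.
#'
#' @param resp Responsibilities from [e_step()].
#' @param x Sink counts.
#' @param lam Nonnegative sparsity penalty (exponential-prior rate).
#' @return Length-(M+1) vector summing to 1; last entry is the unknown.
#' @export
m_step_alpha <- function(resp, x, lam) {
  cvec <- drop(resp %*% x)
  Mp1 <- length(cvec)
  M <- Mp1 - 1L
  if (all(cvec == 0)) st_stop("empty sink: all responsibilities weightless")
  ck <- cvec[seq_len(M)]
  cu <- cvec[Mp1]
  alpha <- numeric(Mp1)
  if (lam == 0) return(cvec / sum(cvec))
  if (cu == 0) {
    # unknown carries no responsibility; either the budget binds or the
    # penalty caps total known mass at sum(c)/lam
    s <- sum(ck)
    if (s >= lam) {
      alpha[seq_len(M)] <- ck / s
    } else {
      alpha[seq_len(M)] <- ck / lam
      alpha[Mp1] <- 1 - s / lam
    }
    return(alpha)
  }
  if (sum(ck) == 0) {
    alpha[Mp1] <- 1
    return(alpha)
  }
  g <- function(nu) sum(ck / (lam + nu)) + cu / nu - 1
  lo <- cu                      # g(cu) = sum(ck)/(lam+cu) >= 0
  hi <- sum(cvec) + lam         # g(hi) < 0 since lam > 0
  nu <- stats::uniroot(g, c(lo, hi), tol = 1e-12 * hi)$root
  for (k in 1:4) {              # Newton polish to the 1e-12 regime
    gp <- -sum(ck / (lam + nu)^2) - cu / nu^2
    nu <- nu - g(nu) / gp
  }
  alpha[seq_len(M)] <- ck / (lam + nu)
  alpha[Mp1] <- cu / nu
  alpha / sum(alpha)
}

#' Penalized observed-data log-likelihood
#'
#' The data terms of the model log-likelihood,
#' \eqn{\ell = \sum_j x_j\log\beta_j + \sum_{i}\sum_j y_{ij}\log\gamma_{ij}}
#' with \eqn{\beta_j = \sum_i\alpha_i\gamma_{ij}} (multinomial coefficients
#' dropped), and the penalized objective
#' \eqn{\ell - \lambda\sum_{i\le M}\alpha_i + M\log\lambda} that the EM
#' ascends. The y-term runs over all M+1 rows, the last being the plug-in
#' unknown pseudo-counts, matching what the \eqn{\gamma} M-step maximizes.
#' Logarithm arguments are clamped below at `clamp_eps` so taxa the mixture
#' cannot explain yield a large finite deficit rather than `-Inf`.
#'
#' @param alpha Length-(M+1) mixing proportions.
#' @param gamma (M+1) x N latent profiles.
#' @param lam Penalty.
#' @param x Sink counts.
#' @param Y (M+1) x N counts including the unknown row.
#' @param clamp_eps Lower clamp for log arguments (default `1e-12`).
#' @return List with `loglik` (data terms only) and `penalized_obj`.
#' @export
penalized_log_likelihood <- function(alpha, gamma, lam, x, Y,
                                     clamp_eps = 1e-12) {
  beta <- drop(crossprod(gamma, alpha))
  ll <- sum(x * log(pmax(beta, clamp_eps)))
  pos <- Y > 0
  ll <- ll + sum(Y[pos] * log(pmax(gamma[pos], clamp_eps)))
  M <- length(alpha) - 1L
  pen <- ll - lam * sum(alpha[seq_len(M)]) + if (lam > 0) M * log(lam) else 0
  list(loglik = ll, penalized_obj = pen)
}

#' Penalized EM for fixed sparsity penalty
#'
#' Alternates [e_step()], [m_step_gamma()] and [m_step_alpha()] from the
#' screening-based initialization until the relative change of the penalized
#' objective falls below `tol` or `max_iter` is reached. The unknown source's
#' pseudo-count row is the plug-in estimate and is held fixed across
#' iterations; its latent profile row still updates. The penalized objective
#' is non-decreasing across iterations (standard EM ascent).
#'
#' @param problem A [build_problem()] result.
#' @param lam Nonnegative penalty.
#' @param init List with `alpha_init` (length M, from [solve_sparse_qp()]),
#'   `gamma_init` (M x N, from [normalize_profiles()]) and `unknown` (from
#'   [init_unknown_profile()]). The initial mixture is the screened
#'   proportions with the remainder \eqn{1-\sum\hat\alpha} assigned to the
#'   unknown; if the screening selected nothing, known sources start uniform
#'   at a total of 50% with 50% unknown.
#' @param tol Relative convergence tolerance on the penalized objective.
#' @param max_iter Maximum EM iterations.
#' @param clamp_eps Lower clamp for log arguments.
#' @return An `em_state` list: `alpha` (named, length M+1, last `"Unknown"`),
#'   `gamma`, `lam`, `loglik`, `penalized_obj`, `n_iter`, `converged`,
#'   `obj_trace`.
#' @export
run_em <- function(problem, lam, init, tol = 1e-6, max_iter = 1000L,
                   clamp_eps = 1e-12) {
  x <- as.numeric(problem$sink)
  M <- nrow(problem$sources)
  N <- length(x)
  a_hat <- init$alpha_init
  if (sum(a_hat) == 0) {
    alpha <- c(rep(0.5 / M, M), 0.5)
  } else {
    alpha <- c(a_hat, max(0, 1 - sum(a_hat)))
    alpha <- alpha / sum(alpha)
  }
  unk <- init$unknown$counts
  g_unk <- if (sum(unk) > 0) unk / sum(unk) else rep(1 / N, N)
  gamma <- rbind(init$gamma_init, g_unk)
  Y <- rbind(unclass(problem$sources), unk)
  obj_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    resp <- e_step(alpha, gamma, x)
    gamma <- m_step_gamma(resp, x, Y)
    alpha <- m_step_alpha(resp, x, lam)
    ll <- penalized_log_likelihood(alpha, gamma, lam, x, Y, clamp_eps)
    if (!is.finite(ll$penalized_obj)) {
      st_stop("non-finite EM objective at iteration ", it)
    }
    trace <- c(trace, ll$penalized_obj)
    n_iter <- it
    if (is.finite(obj_prev) &&
        abs(ll$penalized_obj - obj_prev) <
          tol * max(abs(obj_prev), .Machine$double.eps)) {
      converged <- TRUE
      obj_prev <- ll$penalized_obj
      break
    }
    obj_prev <- ll$penalized_obj
  }
  final <- penalized_log_likelihood(alpha, gamma, lam, x, Y, clamp_eps)
  structure(list(
    alpha = stats::setNames(alpha, c(problem$source_ids, "Unknown")),
    gamma = gamma,
    lam = lam,
    loglik = final$loglik,
    penalized_obj = final$penalized_obj,
    n_iter = n_iter,
    converged = converged,
    obj_trace = trace
  ), class = "em_state")
}

#' @export
print.em_state <- function(x, ...) {
  cat(sprintf(paste0("em_state: lambda = %g, %d iterations (%s), ",
                     "loglik = %.3f, unknown = %.3f\n"),
              x$lam, x$n_iter, if (x$converged) "converged" else "not converged",
              x$loglik, x$alpha[["Unknown"]]))
  sel <- x$alpha[x$alpha > 1e-8]
  cat("selected:", paste(sprintf("%s=%.3f", names(sel), sel), collapse = ", "), "\n")
  invisible(x)
}

#' Grid search over the sparsity penalty
#'
#' Runs [run_em()] once per grid value from the same initialization and
#' returns the state with the highest observed-data log-likelihood (the data
#' terms only; the prior terms \eqn{-\lambda\sum\alpha} and \eqn{M\log\lambda}
#' are excluded from the comparison because \eqn{M\log\lambda} alone would make
#' it monotone in \eqn{\lambda} regardless of fit). Ties go to the larger
#' (sparser) penalty.
#'
#' @inheritParams run_em
#' @param lambda_grid Strictly increasing positive penalties.
#' @return The selected `em_state`, with a `grid` attribute holding a
#'   `data.frame` of (`lambda`, `loglik`, `n_iter`, `converged`) per grid value.
#' @export
grid_search <- function(problem, lambda_grid, init, tol = 1e-6,
                        max_iter = 1000L, clamp_eps = 1e-12) {
  if (length(lambda_grid) == 0) st_stop("empty lambda grid")
  if (any(lambda_grid <= 0)) st_stop("lambda grid must be positive")
  if (any(diff(lambda_grid) <= 0)) st_stop("lambda grid must be strictly increasing")
  states <- lapply(lambda_grid, function(lam) {
    tryCatch(run_em(problem, lam, init, tol, max_iter, clamp_eps),
             error = function(e) {
               st_stop("EM failed at lambda = ", lam, ": ", conditionMessage(e))
             })
  })
  ll <- vapply(states, `[[`, numeric(1), "loglik")
  best <- 1L
  for (k in seq_along(ll)) if (ll[k] >= ll[best]) best <- k
  out <- states[[best]]
  attr(out, "grid") <- data.frame(
    lambda = lambda_grid,
    loglik = ll,
    n_iter = vapply(states, `[[`, integer(1), "n_iter"),
    converged = vapply(states, `[[`, logical(1), "converged")
  )
  out
}

#' Default penalty grid
#' @return The default grid `10^(-8:-2)`.
#' @export
default_lambda_grid <- function() 10^seq(-8, -2)
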