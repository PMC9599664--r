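#' Squared-error loss over the known sources
#'
#' The benchmark's "MSE": the sum of squared deviations between true and
#' estimated proportions over the M known candidate sources,
#' \eqn{\sum_{i=1}^{M}(\alpha_i - \hat\alpha_i)^2}. The conventional mean is
#' available via `mean = TRUE` but the sum is the reported convention.
#'
#' @param alpha_true,alpha_hat Length-M vectors of proportions in \[0, 1\].
#' @param mean Divide by M (default `FALSE`, i.e. report the sum).
#' @return Nonnegative scalar.
#' @export
mse <- function(alpha_true, alpha_hat, mean = FALSE) {
  if (length(alpha_true) != length(alpha_hat)) {
    st_stop("mse: length mismatch (", length(alpha_true), " vs ",
            length(alpha_hat), ")")
  }
  s <- sum((alpha_true - alpha_hat)^2)
  if (mean) s / length(alpha_true) else s
}

#' Absolute error of the unknown proportion
#' @param true_unknown,est_unknown Scalars in \[0, 1\].
#' @return \eqn{|\alpha_{M+1} - \hat\alpha_{M+1}|}.
#' @export
abs_error_unknown <- function(true_unknown, est_unknown) {
  abs(true_unknown - est_unknown)
}

#' False positive rate: mass misattributed to non-contributing sources
#'
#' The total estimated proportion assigned to sources whose true contribution
#' is exactly zero: \eqn{\mathrm{FPR} = \sum_{i: \alpha_i = 0} \hat\alpha_i}.
#' Exact zeros are meaningful because the ground truth is constructed by the
#' simulator, not estimated.
#'
#' @param alpha_true,alpha_hat Length-M vectors over the known sources.
#' @return Scalar in \[0, 1\].
#' @export
false_positive_rate <- function(alpha_true, alpha_hat) {
  if (length(alpha_true) != length(alpha_hat)) {
    st_stop("false_positive_rate: length mismatch")
  }
  sum(alpha_hat[alpha_true == 0])
}

#' Evaluate an estimate against ground truth
#'
#' @param alpha_true,alpha_hat Length-(M+1) named vectors (known sources plus
#'   a final `"Unknown"` entry). Names, when present on both, must match.
#' @return One-row `data.frame` with columns `mse`, `ae_unknown`, `fpr`.
#' @export
evaluation_report <- function(alpha_true, alpha_hat) {
  if (length(alpha_true) != length(alpha_hat)) {
    st_stop("evaluation_report: length mismatch")
  }
  if (!is.null(names(alpha_true)) && !is.null(names(alpha_hat))) {
    mism <- union(setdiff(names(alpha_true), names(alpha_hat)),
                  setdiff(names(alpha_hat), names(alpha_true)))
    if (length(mism)) {
      st_stop("truth/estimate source ids do not match: ",
              paste(mism, collapse = ", "))
    }
    alpha_hat <- alpha_hat[names(alpha_true)]
  }
  M <- length(alpha_true) - 1L
  data.frame(
    mse = mse(alpha_true[seq_len(M)], alpha_hat[seq_len(M)]),
    ae_unknown = abs_error_unknown(alpha_true[M + 1L], alpha_hat[M + 1L]),
    fpr = false_positive_rate(alpha_true[seq_len(M)], alpha_hat[seq_len(M)])
  )
}
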