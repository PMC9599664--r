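#' Track the sources of one sink
#'
#' The full per-sink pipeline: normalize observed source profiles, screen
#' candidates with the L1-penalized constrained least-squares problem,
#' initialize the unknown source from the screening residual, then refine
#' mixing proportions and latent profiles by penalized EM across the sparsity
#' grid, keeping the state with the highest model likelihood.
#'
#' @param problem A [build_problem()] result.
#' @param lambda Penalty for the screening step (default `1e-6`).
#' @param lambda_grid Penalty grid for the EM stage
#'   (default [default_lambda_grid()]).
#' @param em_tol,em_max_iter EM convergence controls.
#' @param support_tol Screening support threshold.
#' @param clamp_eps Likelihood log clamp.
#' @return The selected `em_state` (see [grid_search()]); `alpha` holds the
#'   estimated proportions over the candidate sources plus `"Unknown"`.
#' @examples
#' cfg <- simulation_config(n_taxa = 80, n_candidates = 6, n_contributing = 2,
#'                          n_sinks = 1, unknown_prop = 0.2, seed = 7)
#' ds <- build_dataset(cfg)
#' fit <- track_sink(ds$problems[[1]])
#' round(fit$alpha, 3)
#' @export
track_sink <- function(problem, lambda = 1e-6,
                       lambda_grid = default_lambda_grid(),
                       em_tol = 1e-6, em_max_iter = 1000L,
                       support_tol = 1e-8, clamp_eps = 1e-12) {
  gamma_init <- normalize_profiles(problem)
  x_rel <- as.numeric(problem$sink) / problem$sink_total
  sel <- solve_sparse_qp(x_rel, gamma_init, lambda, support_tol = support_tol)
  unk <- init_unknown_profile(problem, sel)
  init <- list(alpha_init = sel$alpha_init, gamma_init = gamma_init,
               unknown = unk)
  grid_search(problem, lambda_grid, init, tol = em_tol,
              max_iter = em_max_iter, clamp_eps = clamp_eps)
}

#' Unpenalized EM baseline for one sink
#'
#' The same pipeline with no sparsity: least-squares screening without the L1
#' term and a single EM run at zero penalty. Used as the dense reference the
#' sparse estimator is compared against (its false positive rate on nuisance
#' sources is the quantity the sparsity prior is designed to reduce).
#'
#' @inheritParams track_sink
#' @return An `em_state`.
#' @export
track_sink_unpenalized <- function(problem, em_tol = 1e-6,
                                   em_max_iter = 1000L, clamp_eps = 1e-12) {
  gamma_init <- normalize_profiles(problem)
  x_rel <- as.numeric(problem$sink) / problem$sink_total
  sel <- solve_sparse_qp(x_rel, gamma_init, 0)
  unk <- init_unknown_profile(problem, sel)
  init <- list(alpha_init = sel$alpha_init, gamma_init = gamma_init,
               unknown = unk)
  run_em(problem, 0, init, tol = em_tol, max_iter = em_max_iter,
         clamp_eps = clamp_eps)
}

#' Track every sink of a counts/metadata pair and write results
#'
#' File-level driver behind the command-line interface. Reads a count table
#' and metadata, builds one problem per sink (or the one named sink), runs
#' [track_sink()], and writes one proportions TSV per sink into `out_dir`
#' (named `<sink_id>.tsv`), plus `run_config.json` echoing the configuration
#' and a `run_log.tsv` recording the chosen penalty, iteration count and final
#' objective per sink.
#'
#' @param counts_path Count table TSV path.
#' @param metadata_path Metadata TSV path.
#' @param out_dir Output directory.
#' @param sink_id Single sink to process, or `NULL` for all sinks.
#' @param orientation Count-table orientation flag (see [read_count_table()]).
#' @param lambda Screening penalty; when `cv = TRUE` and more than one sink is
#'   present it is replaced by [cross_validate_lambda()] over `lambda_grid`.
#' @param cv Cross-validate the screening penalty (default `FALSE`).
#' @param lambda_grid EM penalty grid.
#' @param seed Seed for the cross-validation split.
#' @inheritParams track_sink
#' @return Invisibly, a named list of `em_state` objects.
#' @export
track_files <- function(counts_path, metadata_path, out_dir, sink_id = NULL,
                        orientation = "taxa_rows", lambda = 1e-6, cv = FALSE,
                        lambda_grid = default_lambda_grid(), em_tol = 1e-6,
                        em_max_iter = 1000L, seed = 1L) {
  table <- read_count_table(counts_path, orientation)
  metadata <- read_metadata(metadata_path)
  sinks <- if (is.null(sink_id)) {
    metadata$SampleID[metadata$SourceSink == "Sink"]
  } else sink_id
  if (length(sinks) == 0) st_stop("no sinks in metadata")
  problems <- lapply(sinks, function(s) build_problem(table, metadata, s))
  names(problems) <- sinks
  if (cv && length(problems) >= 2) {
    lambda <- cross_validate_lambda(problems, lambda_grid, split_seed = seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  states <- lapply(problems, function(pr) {
    track_sink(pr, lambda = lambda, lambda_grid = lambda_grid,
               em_tol = em_tol, em_max_iter = em_max_iter)
  })
  for (s in sinks) {
    write_proportions(states[[s]]$alpha, file.path(out_dir, paste0(s, ".tsv")))
  }
  log_df <- data.frame(
    SinkID = sinks,
    lambda_selected = vapply(states, `[[`, numeric(1), "lam"),
    n_iter = vapply(states, `[[`, integer(1), "n_iter"),
    converged = vapply(states, `[[`, logical(1), "converged"),
    loglik = vapply(states, `[[`, numeric(1), "loglik")
  )
  utils::write.table(log_df, file.path(out_dir, "run_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(command = "track", counts = counts_path, metadata = metadata_path,
         sink_id = sink_id, orientation = orientation, lambda = lambda,
         cv = cv, lambda_grid = lambda_grid, em_tol = em_tol,
         em_max_iter = em_max_iter, seed = seed),
    file.path(out_dir, "run_config.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, null = "null")
  invisible(states)
}

#' Evaluate an estimates file against a truth file
#'
#' Both files follow the proportions dialect (columns `SourceID`,
#' `proportion`, rows = source ids plus `Unknown`); `truth_path` may also be
#' the multi-sink `truth.tsv` written by [write_dataset()], in which case
#' `sink_id` names the column to compare against.
#'
#' @param estimates_path,truth_path TSV paths.
#' @param sink_id Truth column for the multi-sink layout.
#' @return One-row `data.frame` with `mse`, `ae_unknown`, `fpr`.
#' @export
evaluate_files <- function(estimates_path, truth_path, sink_id = NULL) {
  est <- read_proportions(estimates_path)
  df <- utils::read.delim(truth_path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if ("proportion" %in% colnames(df)) {
    truth <- stats::setNames(as.numeric(df$proportion), df$SourceID)
  } else {
    if (is.null(sink_id) || !sink_id %in% colnames(df)) {
      st_stop("multi-sink truth file: supply sink_id matching one of: ",
              paste(setdiff(colnames(df), "SourceID"), collapse = ", "))
    }
    truth <- stats::setNames(as.numeric(df[[sink_id]]), df$SourceID)
  }
  evaluation_report(truth, est)
}
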