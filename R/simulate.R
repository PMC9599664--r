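#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic source/sink generator.
#' Defaults mirror the benchmark design: candidate panels of 50 sources of
#' which 10 truly contribute, every source subsampled to 10,000 reads, sinks
#' drawn at the same depth, and sparse Pareto-distributed mixing vectors.
#'
#' @param n_taxa Number of taxa in the synthetic community (default 500).
#' @param n_candidates M, number of observed candidate sources (default 50).
#' @param n_contributing K <= M, number of truly contributing sources
#'   (default 10).
#' @param source_depth Reads per source after subsampling (default 10000).
#' @param sink_depth Reads per sink (default 10000).
#' @param unknown_prop True unknown-source proportion, in \[0, 0.9\]
#'   (default 0.3).
#' @param pareto_shape Shape of the Pareto mixing-weight distribution
#'   (default 1.0; heavy-tailed, a few dominant contributors).
#' @param n_sinks Number of sinks per dataset (default 30).
#' @param seed Integer RNG seed; every random draw of the dataset flows from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 500L, n_candidates = 50L,
                              n_contributing = 10L, source_depth = 10000L,
                              sink_depth = 10000L, unknown_prop = 0.3,
                              pareto_shape = 1.0, n_sinks = 30L, seed = 1L) {
  if (n_contributing > n_candidates) st_stop("n_contributing must be <= n_candidates")
  if (n_contributing < 1 || n_candidates < 1) st_stop("need at least one source")
  if (unknown_prop < 0 || unknown_prop > 0.9) st_stop("unknown_prop must be in [0, 0.9]")
  if (source_depth <= 0 || sink_depth <= 0) st_stop("depths must be positive")
  if (pareto_shape <= 0) st_stop("pareto_shape must be positive")
  structure(list(
    n_taxa = as.integer(n_taxa), n_candidates = as.integer(n_candidates),
    n_contributing = as.integer(n_contributing),
    source_depth = as.integer(source_depth), sink_depth = as.integer(sink_depth),
    unknown_prop = unknown_prop, pareto_shape = pareto_shape,
    n_sinks = as.integer(n_sinks), seed = as.integer(seed)
  ), class = "simulation_config")
}

# Subsample a count vector to `depth` reads without replacement
# (multivariate hypergeometric on the read level).
subsample_counts <- function(y, depth) {
  if (sum(y) < depth) {
    st_stop("cannot subsample ", depth, " reads from a sample with only ",
            sum(y), " reads")
  }
  reads <- sample(rep.int(seq_along(y), y), depth)
  tabulate(reads, nbins = length(y))
}

#' Draw source count profiles at fixed depth
#'
#' Produces M+1 sources (the last is the hidden unknown), each with exactly
#' `source_depth` reads. When `base_sources` is supplied, each source is a
#' without-replacement subsample of one column of real counts; otherwise each
#' source's underlying relative abundance is an independent seeded log-normal
#' weight vector (normalized), emulating the heavy right-skew of real
#' communities, and counts are one multinomial draw at `source_depth`.
#'
#' Uses the current RNG state; seed upstream (see [build_dataset()]).
#'
#' @param config A [simulation_config()].
#' @param base_sources Optional [count_table()] with at least M+1 columns,
#'   each totalling at least `source_depth` reads.
#' @return List with `counts` ((M+1) x n_taxa integer matrix; rows sum to
#'   `source_depth`) and `profiles` (the underlying relative abundances).
#' @export
draw_source_profiles <- function(config, base_sources = NULL) {
  M1 <- config$n_candidates + 1L
  if (!is.null(base_sources)) {
    if (ncol(base_sources) < M1) {
      st_stop("base_sources must provide at least M+1 = ", M1, " samples")
    }
    cols <- sample(ncol(base_sources), M1)
    counts <- t(vapply(cols, function(k) {
      subsample_counts(as.numeric(base_sources[, k]), config$source_depth)
    }, numeric(nrow(base_sources))))
    profiles <- sweep(counts, 1, rowSums(counts), "/")
  } else {
    profiles <- t(vapply(seq_len(M1), function(i) {
      w <- stats::rlnorm(config$n_taxa, meanlog = 0, sdlog = 2)
      w / sum(w)
    }, numeric(config$n_taxa)))
    counts <- t(apply(profiles, 1, function(p) {
      drop(stats::rmultinom(1, config$source_depth, p))
    }))
  }
  storage.mode(counts) <- "integer"
  list(counts = counts, profiles = profiles)
}

#' Draw a sparse mixing vector
#'
#' K Pareto-distributed weights scaled to sum to `1 - unknown_prop`, with the
#' unknown proportion appended, so the full vector sums to 1.
#'
#' @param K Number of contributing sources.
#' @param unknown_prop Unknown-source proportion in \[0, 1).
#' @param pareto_shape Pareto shape parameter (scale fixed at 1).
#' @return Length-(K+1) vector; last entry is exactly `unknown_prop`.
#' @export
draw_mixing_proportions <- function(K, unknown_prop, pareto_shape = 1.0) {
  stopifnot(K >= 1, unknown_prop >= 0, unknown_prop < 1)
  w <- (1 - stats::runif(K))^(-1 / pareto_shape)   # Pareto(1, shape) by inversion
  c(w / sum(w) * (1 - unknown_prop), unknown_prop)
}

#' Generate one sink by multinomial mixing
#'
#' One multinomial draw of `sink_depth` reads from the mixed profile
#' \eqn{\beta = \sum_i \alpha_i \gamma_i}.
#'
#' @param profiles (K+1) x N row-stochastic matrix (contributing sources plus
#'   the unknown source's profile).
#' @param alpha Length-(K+1) mixing vector summing to 1.
#' @param sink_depth Number of reads to draw.
#' @return Length-N integer count vector totalling `sink_depth`.
#' @export
generate_sink <- function(profiles, alpha, sink_depth) {
  stopifnot(nrow(profiles) == length(alpha),
            abs(sum(alpha) - 1) < 1e-9, all(alpha >= 0))
  beta <- drop(crossprod(profiles, alpha))
  drop(stats::rmultinom(1, sink_depth, beta))
}

#' Generate shuffled-abundance nuisance sources
#'
#' Builds synthetic non-contributing sources by shuffling the abundances of
#' real ones: each synthetic source expresses \eqn{T_i} taxa, with
#' \eqn{T_i \sim \mathrm{Unif}[\min_j T_j, \max_j T_j]} over the real sources'
#' nonzero-taxon counts; the expressed taxa are chosen uniformly without
#' replacement, and each receives a count drawn without replacement from the
#' pooled nonzero counts of all real sources (draws are without replacement
#' within each synthetic source; the pool is replenished between sources,
#' without which a 50-source synthetic panel could not be built from 6 real
#' sources).
#'
#' @param real_sources A [count_table()] of the real sources.
#' @param n_nuisance Number of synthetic sources to generate.
#' @return A [count_table()] with samples `Synthetic1..n`.
#' @export
generate_nuisance_sources <- function(real_sources, n_nuisance) {
  stopifnot(inherits(real_sources, "count_table"), n_nuisance >= 1)
  n_taxa <- nrow(real_sources)
  t_real <- colSums(real_sources > 0)
  pool <- as.numeric(real_sources[real_sources > 0])
  out <- matrix(0L, nrow = n_taxa, ncol = n_nuisance,
                dimnames = list(rownames(real_sources),
                                paste0("Synthetic", seq_len(n_nuisance))))
  for (i in seq_len(n_nuisance)) {
    t_range <- seq.int(min(t_real), max(t_real))
    t_i <- t_range[sample.int(length(t_range), 1)]
    if (t_i > length(pool)) {
      st_stop("pool of nonzero counts (", length(pool),
              ") smaller than requested taxa per synthetic source (", t_i, ")")
    }
    taxa <- sample(n_taxa, t_i)
    take <- sample(length(pool), t_i)
    out[taxa, i] <- as.integer(pool[take])
  }
  count_table(out)
}

#' Build a full synthetic source-tracking dataset
#'
#' Composes the generator: draws M candidate sources plus one hidden unknown
#' source at fixed depth, designates K contributing sources uniformly at
#' random among the candidates, and generates `n_sinks` sinks, each from a
#' freshly drawn sparse mixing vector over the contributing sources with the
#' unknown proportion appended. The hidden unknown source's counts are
#' withheld from the candidate panel handed to inference; ground-truth mixing
#' proportions are recorded per sink. All randomness flows from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param base_sources Optional real [count_table()] to subsample sources from.
#' @return A `sim_dataset` list: `counts` ([count_table()], taxa x (M sources +
#'   n_sinks sinks)), `metadata` (data.frame in the I/O dialect), `problems`
#'   (list of [build_problem()] results, one per sink), `true_alpha`
#'   (n_sinks x (M+1) matrix, last column `"Unknown"`), `contributing_ids`,
#'   `unknown_counts` (the withheld source), `config`.
#' @export
build_dataset <- function(config, base_sources = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  M <- config$n_candidates
  K <- config$n_contributing
  local_seed(config$seed, {
    src <- draw_source_profiles(config, base_sources)
    contributing <- sort(sample(M, K))
    src_rel <- sweep(src$counts, 1, rowSums(src$counts), "/")
    mix_profiles <- src_rel[c(contributing, M + 1L), , drop = FALSE]
    sinks <- matrix(0L, nrow = config$n_sinks, ncol = ncol(src$counts))
    true_alpha <- matrix(0, nrow = config$n_sinks, ncol = M + 1L)
    for (s in seq_len(config$n_sinks)) {
      a <- draw_mixing_proportions(K, config$unknown_prop, config$pareto_shape)
      sinks[s, ] <- generate_sink(mix_profiles, a, config$sink_depth)
      true_alpha[s, contributing] <- a[seq_len(K)]
      true_alpha[s, M + 1L] <- config$unknown_prop
    }
    src_ids <- sprintf("Source%02d", seq_len(M))
    sink_ids <- sprintf("Sink%02d", seq_len(config$n_sinks))
    taxa_ids <- sprintf("taxon%04d", seq_len(ncol(src$counts)))
    colnames(true_alpha) <- c(src_ids, "Unknown")
    rownames(true_alpha) <- sink_ids
    counts <- count_table(
      t(rbind(src$counts[seq_len(M), , drop = FALSE], sinks)),
      taxa_ids = taxa_ids, sample_ids = c(src_ids, sink_ids)
    )
    metadata <- data.frame(
      SampleID = c(src_ids, sink_ids),
      Env = c(sprintf("sim_env%02d", seq_len(M)), rep("sim_sink", config$n_sinks)),
      SourceSink = c(rep("Source", M), rep("Sink", config$n_sinks)),
      id = NA_character_, stringsAsFactors = FALSE
    )
    problems <- lapply(sink_ids, function(sid) build_problem(counts, metadata, sid))
    names(problems) <- sink_ids
    structure(list(
      counts = counts, metadata = metadata, problems = problems,
      true_alpha = true_alpha, contributing_ids = src_ids[contributing],
      unknown_counts = stats::setNames(as.numeric(src$counts[M + 1L, ]), taxa_ids),
      config = config
    ), class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0("sim_dataset: %d candidate sources (%d contributing), ",
                     "%d sinks, %d taxa, unknown = %.0f%%\n"),
              x$config$n_candidates, x$config$n_contributing,
              x$config$n_sinks, nrow(x$counts), 100 * x$config$unknown_prop))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits four artifacts into `dir`: `counts.tsv` (taxa x samples),
#' `metadata.tsv` (I/O dialect), `truth.tsv` (rows = source ids plus
#' `Unknown`, one column of true proportions per sink) and `config.json`
#' (the configuration echoed verbatim).
#'
#' @param dataset A [build_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(dataset$counts, file.path(dir, "counts.tsv"))
  utils::write.table(dataset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  truth <- data.frame(SourceID = colnames(dataset$true_alpha),
                      t(dataset$true_alpha), check.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(dataset$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
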