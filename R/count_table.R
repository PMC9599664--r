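#' @keywords internal
st_stop <- function(..., class = "sparsetrack_error", call. = FALSE) {
  stop(structure(
    class = c(class, "sparsetrack_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

#' Construct a taxon-by-sample count table
#'
#' The universal exchange object of the package: a nonnegative integer matrix
#' of read counts with taxa as rows and samples as columns, plus unique
#' identifiers for both axes. Relative-abundance input is rejected because the
#' multinomial model downstream requires counts.
#'
#' @param counts Nonnegative integer matrix, taxa x samples.
#' @param taxa_ids Character vector of unique taxon identifiers (defaults to
#'   `rownames(counts)`).
#' @param sample_ids Character vector of unique sample identifiers (defaults to
#'   `colnames(counts)`).
#' @return An object of class `count_table`: the integer matrix with
#'   `dimnames` set to the identifiers.
#' @examples
#' ct <- count_table(matrix(c(5L, 1L, 0L, 3L, 2L, 4L), nrow = 2,
#'                          dimnames = list(c("tA", "tB"), c("s1", "s2", "s3"))))
#' colSums(ct)
#' @export
count_table <- function(counts, taxa_ids = rownames(counts),
                        sample_ids = colnames(counts)) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(taxa_ids) || is.null(sample_ids)) {
    st_stop("count_table requires taxon and sample identifiers")
  }
  taxa_ids <- as.character(taxa_ids)
  sample_ids <- as.character(sample_ids)
  if (length(taxa_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    st_stop("identifier lengths do not match count matrix dimensions")
  }
  if (anyDuplicated(taxa_ids)) {
    st_stop("duplicate taxon identifiers: ",
            paste(unique(taxa_ids[duplicated(taxa_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    st_stop("duplicate sample identifiers: ",
            paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (any(!is.finite(counts))) st_stop("counts contain non-finite values")
  if (any(counts < 0)) st_stop("counts must be nonnegative")
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    st_stop("counts must be integers (the model is multinomial over reads; ",
            "rescale relative abundances to counts first); first offending ",
            "cell: taxon '", taxa_ids[bad[1]], "', sample '",
            sample_ids[bad[2]], "'")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(taxa_ids, sample_ids)
  structure(counts, class = c("count_table", "matrix", "array"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Read a tab-delimited count table
#'
#' Reads a TSV whose first column holds identifiers and whose header holds the
#' identifiers of the other axis. The caller must state the orientation; no
#' auto-detection is attempted because silently transposed tables are a
#' classic source-tracking bug.
#'
#' @param path Path to a tab-delimited text file. For `orientation =
#'   "taxa_rows"` the first header cell is `TaxonID` and columns are samples;
#'   for `"samples_rows"` the first header cell is `SampleID` and columns are
#'   taxa.
#' @param orientation Either `"taxa_rows"` or `"samples_rows"`.
#' @return A [count_table()] in canonical taxa x samples orientation.
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) st_stop("count table file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) st_stop("count table needs an identifier column plus at least one data column")
  row_ids <- df[[1]]
  col_ids <- colnames(df)[-1]
  m <- matrix(NA_real_, nrow = nrow(df), ncol = length(col_ids))
  for (k in seq_along(col_ids)) {
    v <- suppressWarnings(as.numeric(df[[k + 1]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      st_stop("cell is not a nonnegative integer at row '", row_ids[bad[1]],
              "', column '", col_ids[k], "' (value '", df[[k + 1]][bad[1]], "')")
    }
    m[, k] <- v
  }
  if (orientation == "taxa_rows") {
    count_table(m, taxa_ids = row_ids, sample_ids = col_ids)
  } else {
    count_table(t(m), taxa_ids = col_ids, sample_ids = row_ids)
  }
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; a write/read round trip reproduces the
#' table exactly (integer counts, identifier order preserved).
#'
#' @param x A [count_table()].
#' @param path Output file path.
#' @param orientation Layout to write; see [read_count_table()].
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  if (orientation == "taxa_rows") {
    df <- data.frame(TaxonID = rownames(x), unclass(x), check.names = FALSE)
  } else {
    df <- data.frame(SampleID = colnames(x), t(unclass(x)), check.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sink/source sample metadata
#'
#' Expects a TSV with header columns `SampleID`, `Env`, `SourceSink` and an
#' optional `id` column grouping a sink with its designated candidate sources.
#' `SourceSink` must be `Source` or `Sink` (case-insensitive; canonicalized on
#' read).
#'
#' @param path Path to the metadata TSV.
#' @return A `data.frame` with columns `SampleID`, `Env`, `SourceSink`
#'   (canonical `"Source"`/`"Sink"`) and `id` (`NA` when absent).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) st_stop("metadata file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  required <- c("SampleID", "Env", "SourceSink")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    st_stop("metadata is missing required column(s): ",
            paste(missing, collapse = ", "), class = "sparsetrack_io_error")
  }
  role <- tolower(df$SourceSink)
  bad <- which(!role %in% c("source", "sink"))
  if (length(bad)) {
    st_stop("unknown SourceSink value '", df$SourceSink[bad[1]],
            "' for sample '", df$SampleID[bad[1]],
            "' (allowed: Source, Sink)")
  }
  if (anyDuplicated(df$SampleID)) {
    st_stop("duplicate SampleID in metadata: ",
            paste(unique(df$SampleID[duplicated(df$SampleID)]), collapse = ", "))
  }
  data.frame(
    SampleID = df$SampleID,
    Env = df$Env,
    SourceSink = ifelse(role == "source", "Source", "Sink"),
    id = if ("id" %in% colnames(df)) df$id else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Assemble an aligned source/sink problem
#'
#' Extracts one sink vector and its candidate source matrix from a count table,
#' aligned on a shared taxon axis. The taxon axis is the union of taxa observed
#' (nonzero) in the sink or in any selected source, zero-filled elsewhere, so
#' sink taxa absent from every source stay visible to the unknown-source
#' machinery. Source order follows metadata order; when the sink carries a
#' non-missing `id`, candidates are restricted to sources sharing that `id`.
#'
#' @param table A [count_table()].
#' @param metadata Metadata `data.frame` as returned by [read_metadata()].
#' @param sink_id Sample identifier of the sink; must be labeled `Sink`.
#' @return An object of class `source_sink_problem`: a list with elements
#'   `sink` (named integer vector, length N), `sources` (M x N integer matrix),
#'   `taxon_ids`, `source_ids`, `source_totals`, `sink_total`, `sink_id`.
#' @export
build_problem <- function(table, metadata, sink_id) {
  stopifnot(inherits(table, "count_table"))
  idx <- match(sink_id, metadata$SampleID)
  if (is.na(idx)) st_stop("sink '", sink_id, "' not present in metadata")
  if (metadata$SourceSink[idx] != "Sink") {
    st_stop("sample '", sink_id, "' is labeled ", metadata$SourceSink[idx],
            ", not Sink")
  }
  src_meta <- metadata[metadata$SourceSink == "Source", , drop = FALSE]
  pair <- metadata$id[idx]
  if (!is.na(pair) && pair != "") {
    src_meta <- src_meta[!is.na(src_meta$id) & src_meta$id == pair, , drop = FALSE]
  }
  src_ids <- setdiff(src_meta$SampleID, sink_id)
  if (length(src_ids) < 1) st_stop("no candidate sources for sink '", sink_id, "'")
  absent <- setdiff(c(sink_id, src_ids), colnames(table))
  if (length(absent)) {
    st_stop("metadata sample(s) absent from count table: ",
            paste(absent, collapse = ", "))
  }
  x <- table[, sink_id]
  Y <- t(table[, src_ids, drop = FALSE])   # M x N
  keep <- x > 0 | colSums(Y) > 0
  x <- x[keep]
  Y <- Y[, keep, drop = FALSE]
  if (sum(x) == 0) st_stop("sink '", sink_id, "' has zero total reads")
  ctot <- rowSums(Y)
  if (any(ctot == 0)) {
    st_stop("source '", src_ids[which(ctot == 0)[1]], "' has zero total reads")
  }
  structure(list(
    sink = x,
    sources = Y,
    taxon_ids = names(x),
    source_ids = src_ids,
    source_totals = as.numeric(ctot),
    sink_total = as.numeric(sum(x)),
    sink_id = sink_id
  ), class = "source_sink_problem")
}

#' @export
print.source_sink_problem <- function(x, ...) {
  cat(sprintf("source_sink_problem: sink '%s' (%d reads), %d candidate sources, %d taxa\n",
              x$sink_id, as.integer(x$sink_total), length(x$source_ids),
              length(x$taxon_ids)))
  invisible(x)
}

#' Write estimated mixing proportions to TSV
#'
#' Rows are the candidate source identifiers plus the literal `Unknown`;
#' proportions are printed with fixed 6-decimal formatting and renormalized
#' post hoc so the printed column sums to exactly 1.000000.
#'
#' @param alpha Named numeric vector over sources plus `Unknown`, summing to 1.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(alpha, path) {
  r <- round(alpha, 6)
  # push the rounding remainder onto the largest entry so the column sums to 1
  r[which.max(r)] <- r[which.max(r)] + (1 - sum(r))
  df <- data.frame(SourceID = names(alpha), proportion = sprintf("%.6f", r))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a proportions TSV written by [write_proportions()]
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_proportions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("SourceID", "proportion") %in% colnames(df))) {
    st_stop("proportions file must have columns SourceID and proportion")
  }
  stats::setNames(as.numeric(df$proportion), df$SourceID)
}
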