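#' LFQ intensity matrix
#'
#' Container for protein-group LFQ intensities: a proteins x samples matrix
#' with explicit missingness (`NA`), a sample table keying each column by
#' condition (`POS` = enzyme-active, `NEG` = enzyme-inactive), chase time in
#' minutes and replicate, and a scale flag (`"RAW"` linear intensities or
#' `"LOG2"`).
#'
#' On the RAW scale all observed values must be non-negative; a raw intensity
#' of 0 is the conventional encoding of a missing value and is converted to
#' `NA` by [read_protein_groups()]. On the LOG2 scale missingness is always
#' explicit `NA`, never 0.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (`"POS"`/`"NEG"`), `time_min`, `replicate`; one row per matrix column,
#'   in column order.
#' @param scale `"RAW"` or `"LOG2"`.
#' @return An object of class `lfq_matrix`.
#' @export
lfq_matrix <- function(values, samples, scale = c("RAW", "LOG2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_data("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop_data("`values` must have protein ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop_data("duplicate protein ids in intensity matrix")
  req <- c("sample_id", "condition", "time_min", "replicate")
  if (!all(req %in% names(samples)))
    stop_data("`samples` must have columns: %s", paste(req, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop_data("sample table rows (%d) != matrix columns (%d)",
              nrow(samples), ncol(values))
  if (!all(samples$condition %in% c("POS", "NEG")))
    stop_data("sample condition must be 'POS' or 'NEG'")
  key <- paste(samples$condition, samples$time_min, samples$replicate)
  if (anyDuplicated(key))
    stop_data("duplicate (condition, time, replicate) sample keys")
  if (scale == "RAW" && any(values < 0, na.rm = TRUE))
    stop_data("RAW-scale intensities must be >= 0")
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = as.data.frame(samples),
                 scale = scale),
            class = "lfq_matrix")
}

#' @export
print.lfq_matrix <- function(x, ...) {
  cat(sprintf("lfq_matrix: %d proteins x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  time points (min): %s\n",
              paste(sort(unique(x$samples$time_min)), collapse = ", ")))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.lfq_matrix <- function(x) dim(x$values)

#' Protein identifiers of an LFQ matrix
#' @param x an `lfq_matrix`.
#' @return Character vector of protein ids.
#' @export
protein_ids <- function(x) rownames(x$values)

#' Time points present in an LFQ matrix
#' @param x an `lfq_matrix`.
#' @return Sorted numeric vector of chase times in minutes.
#' @export
time_points <- function(x) sort(unique(x$samples$time_min))

# Column indices for a condition (and optionally a time point).
sample_cols <- function(x, condition, time_min = NULL) {
  sel <- x$samples$condition == condition
  if (!is.null(time_min)) sel <- sel & x$samples$time_min == time_min
  which(sel)
}

#' Fraction of missing entries
#' @param x an `lfq_matrix`.
#' @return Scalar fraction of `NA` cells.
#' @export
missing_fraction <- function(x) mean(is.na(x$values))

#' Pearson correlation between replicate columns
#'
#' Quality-control statistic mirroring standard LFQ replicate checks: for
#' every (condition, time) group with at least two replicates, the Pearson
#' correlation between each pair of replicate columns, computed on cells
#' observed in both.
#'
#' @param x an `lfq_matrix` (any scale; correlations are computed on the
#'   values as stored, so log-transform first for the usual QC).
#' @return data.frame with columns `condition`, `time_min`, `replicate_a`,
#'   `replicate_b`, `pearson`, `n_pairs`.
#' @export
replicate_correlation <- function(x) {
  out <- list()
  groups <- unique(x$samples[, c("condition", "time_min")])
  for (g in seq_len(nrow(groups))) {
    cols <- sample_cols(x, groups$condition[g], groups$time_min[g])
    if (length(cols) < 2) next
    reps <- x$samples$replicate[cols]
    for (i in seq_along(cols)) for (j in seq_along(cols)) {
      if (i >= j) next
      a <- x$values[, cols[i]]; b <- x$values[, cols[j]]
      ok <- !is.na(a) & !is.na(b)
      out[[length(out) + 1L]] <- data.frame(
        condition = groups$condition[g], time_min = groups$time_min[g],
        replicate_a = reps[i], replicate_b = reps[j],
        pearson = if (sum(ok) >= 3) cor(a[ok], b[ok]) else NA_real_,
        n_pairs = sum(ok))
    }
  }
  do.call(rbind, out)
}
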