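#' Read a protein-groups LFQ table
#'
#' Ingests a MaxQuant-style tab-separated protein-groups table: protein ids
#' from `Protein IDs`, intensities from the `LFQ intensity <sample>` columns.
#' Rows flagged in `Reverse` or `Potential contaminant` (marked `"+"`) are
#' removed when `drop_flagged` is `TRUE`; raw intensity 0 is converted to
#' missing.
#'
#' Sample keys are taken from `column_map` when given (a data.frame with
#' columns `column`, `condition`, `time_min`, `replicate`); otherwise sample
#' names of the form `POS_t10_r2` are parsed from the LFQ column headers.
#'
#' @param path file path.
#' @param column_map optional sample-key mapping (see above).
#' @param drop_flagged drop decoy/contaminant-flagged rows (default `TRUE`).
#' @return An [lfq_matrix()] on the RAW scale.
#' @export
read_protein_groups <- function(path, column_map = NULL, drop_flagged = TRUE) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- intersect(c("Protein IDs", "protein_id"), names(df))[1]
  if (is.na(id_col)) stop_data("no 'Protein IDs' column in %s", path)
  if (drop_flagged) {
    flagged <- rep(FALSE, nrow(df))
    for (fc in intersect(c("Reverse", "Potential contaminant"), names(df)))
      flagged <- flagged | (!is.na(df[[fc]]) & df[[fc]] == "+")
    df <- df[!flagged, , drop = FALSE]
  }
  if (anyDuplicated(df[[id_col]]))
    stop_data("duplicate protein ids in %s", path)

  if (is.null(column_map)) {
    lfq_cols <- grep("^LFQ intensity ", names(df), value = TRUE)
    if (!length(lfq_cols)) stop_data("no 'LFQ intensity' columns in %s", path)
    sample_id <- sub("^LFQ intensity ", "", lfq_cols)
    m <- regmatches(sample_id,
                    regexec("^(POS|NEG)_t([0-9.]+)_r([0-9]+)$", sample_id))
    if (any(lengths(m) != 4))
      stop_data("cannot parse sample keys from LFQ column names; provide column_map")
    column_map <- data.frame(
      column = lfq_cols,
      condition = vapply(m, `[`, character(1), 2),
      time_min = as.numeric(vapply(m, `[`, character(1), 3)),
      replicate = as.integer(vapply(m, `[`, character(1), 4)))
  } else {
    req <- c("column", "condition", "time_min", "replicate")
    if (!all(req %in% names(column_map)))
      stop_data("column_map must have columns: %s", paste(req, collapse = ", "))
    missing_cols <- setdiff(column_map$column, names(df))
    if (length(missing_cols))
      stop_data("mapped column(s) not in table: %s",
                paste(missing_cols, collapse = ", "))
  }
  for (tt in unique(column_map$time_min)) {
    conds <- column_map$condition[column_map$time_min == tt]
    if (!all(c("POS", "NEG") %in% conds))
      stop_data("time point %g lacks a POS or NEG sample in column_map", tt)
  }
  vals <- as.matrix(df[, column_map$column, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df[[id_col]]
  vals[vals == 0] <- NA  # raw 0 encodes missing
  samples <- data.frame(sample_id = sub("^LFQ intensity ", "",
                                        column_map$column),
                        condition = column_map$condition,
                        time_min = column_map$time_min,
                        replicate = column_map$replicate)
  lfq_matrix(vals, samples, scale = "RAW")
}

#' Log2-transform a RAW intensity matrix
#'
#' @param matrix an [lfq_matrix()] on the RAW scale.
#' @return The matrix on the LOG2 scale; missing values preserved.
#' @export
log_transform <- function(matrix) {
  if (matrix$scale != "RAW") stop_data("matrix is already on the LOG2 scale")
  if (any(matrix$values < 0, na.rm = TRUE))
    stop_data("negative raw intensity encountered")
  if (any(matrix$values == 0, na.rm = TRUE))
    stop_data("raw intensity 0 must be encoded as missing before transform")
  matrix$values <- log2(matrix$values)
  matrix$scale <- "LOG2"
  matrix
}

#' Filter proteins by valid values
#'
#' A protein is retained iff at some time point *both* conditions have at
#' least `min_valid_per_group` observed replicates — the most permissive rule
#' still compatible with computing a POS/NEG ratio at one time point.
#' Retained proteins keep all columns.
#'
#' @param matrix an [lfq_matrix()] on the LOG2 scale.
#' @param min_valid_per_group minimum observed replicates per condition
#'   (default 1).
#' @return Filtered [lfq_matrix()].
#' @export
filter_valid_values <- function(matrix, min_valid_per_group = 1) {
  if (matrix$scale != "LOG2") stop_data("filter expects a LOG2-scale matrix")
  nrep <- min(table(matrix$samples$condition, matrix$samples$time_min))
  if (min_valid_per_group > nrep)
    stop_config("min_valid_per_group (%d) exceeds replicate count (%d)",
                min_valid_per_group, nrep)
  keep <- rep(FALSE, nrow(matrix$values))
  for (tt in time_points(matrix)) {
    npos <- rowSums(!is.na(matrix$values[, sample_cols(matrix, "POS", tt),
                                         drop = FALSE]))
    nneg <- rowSums(!is.na(matrix$values[, sample_cols(matrix, "NEG", tt),
                                         drop = FALSE]))
    keep <- keep | (npos >= min_valid_per_group & nneg >= min_valid_per_group)
  }
  matrix$values <- matrix$values[keep, , drop = FALSE]
  matrix
}

#' Impute missing values from a downshifted normal
#'
#' Each missing cell in sample column s is replaced by a draw from
#' `Normal(mu_s - downshift * sigma_s, (width * sigma_s)^2)`, where `mu_s`
#' and `sigma_s` are the observed mean and SD of that column — the de-facto
#' standard (Perseus-default) model of values missing because they fall
#' below the detection limit. Observed cells are never altered.
#'
#' @param matrix an [lfq_matrix()] on the LOG2 scale.
#' @param width SD multiplier of the imputation distribution (default 0.3).
#' @param downshift mean downshift in column SDs (default 1.8).
#' @param seed integer seed; imputation is deterministic given the seed.
#' @return Fully observed [lfq_matrix()].
#' @export
impute_downshifted <- function(matrix, width = 0.3, downshift = 1.8,
                               seed = 1L) {
  if (matrix$scale != "LOG2") stop_data("imputation expects a LOG2-scale matrix")
  vals <- matrix$values
  withr::with_seed(seed, {
    for (j in seq_len(ncol(vals))) {
      obs <- vals[, j][!is.na(vals[, j])]
      miss <- which(is.na(vals[, j]))
      if (!length(miss)) next
      if (length(obs) < 2)
        stop_data("column %s has < 2 observed values; SD undefined",
                  colnames(vals)[j])
      mu <- mean(obs); sigma <- sd(obs)
      vals[miss, j] <- rnorm(length(miss), mu - downshift * sigma,
                             width * sigma)
    }
  })
  matrix$values <- vals
  matrix
}

#' Median-center sample columns
#'
#' Optional between-sample normalization: subtracts each column's observed
#' median and adds back the grand median, equalizing column medians. LFQ
#' intensities are usually pre-normalized upstream, so this is off by
#' default in the pipeline.
#'
#' @param matrix an [lfq_matrix()] on the LOG2 scale.
#' @return Centered [lfq_matrix()].
#' @export
median_center <- function(matrix) {
  if (matrix$scale != "LOG2") stop_data("median centering expects LOG2 scale")
  meds <- apply(matrix$values, 2, median, na.rm = TRUE)
  grand <- median(meds)
  matrix$values <- sweep(matrix$values, 2, meds - grand)
  matrix
}
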