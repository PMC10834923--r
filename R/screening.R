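#' Per-time-point log2 abundance ratios
#'
#' For every protein, the mean over POS (enzyme-active) replicates minus the
#' mean over NEG (enzyme-inactive) replicates at the given time point, on
#' the log2 scale — the log2 of the conventional FC(+/-) fold change.
#'
#' @param matrix a fully imputed [lfq_matrix()] on the LOG2 scale.
#' @param time_min chase time in minutes.
#' @return Object of class `ratio_table`: data.frame with columns
#'   `protein_id`, `log2fc`, `qvalue` (`NA` until
#'   [estimate_empirical_fdr()]); attribute `time_min`.
#' @export
compute_log_ratios <- function(matrix, time_min) {
  if (matrix$scale != "LOG2") stop_data("ratios require a LOG2-scale matrix")
  if (anyNA(matrix$values))
    stop_data("matrix must be fully imputed before computing ratios")
  pos <- sample_cols(matrix, "POS", time_min)
  neg <- sample_cols(matrix, "NEG", time_min)
  if (!length(pos) || !length(neg))
    stop_data("time point %g lacks POS or NEG samples", time_min)
  out <- data.frame(protein_id = protein_ids(matrix),
                    log2fc = rowMeans(matrix$values[, pos, drop = FALSE]) -
                             rowMeans(matrix$values[, neg, drop = FALSE]),
                    qvalue = NA_real_)
  rownames(out) <- NULL
  attr(out, "time_min") <- time_min
  class(out) <- c("ratio_table", "data.frame")
  out
}

# Mirror empirical FDR on centered ratios x (no centering applied here).
# raw(r) = (pseudocount + #{x_j <= -r}) / #{x_j >= r} for r > 0, with ties
# counted on both closed sides; q_i = min over thresholds t <= r_i of raw(t)
# (cumulative minimum in ascending ratio order), clipped to [0, 1];
# non-positive centered ratios get q = 1.
mirror_qvalues <- function(x, pseudocount = 1) {
  n <- length(x)
  q <- rep(1, n)
  pos <- which(x > 0)
  if (!length(pos)) return(q)
  r <- x[pos]
  # closed-inequality counts on both sides (ties count on both)
  n_pos <- vapply(r, function(v) sum(x >= v), integer(1))
  n_neg <- vapply(r, function(v) sum(x <= -v), integer(1))
  raw <- (pseudocount + n_neg) / n_pos
  ord <- order(r)
  q[pos[ord]] <- pmin(1, cummin(raw[ord]))
  q
}

# Gaussian-null variant: null scale fitted to the central 50% of the
# centered distribution; expected null exceedances replace mirror counts.
gaussian_qvalues <- function(x) {
  n <- length(x)
  q <- rep(1, n)
  pos <- which(x > 0)
  if (!length(pos)) return(q)
  s <- diff(quantile(x, c(0.25, 0.75))) / (2 * qnorm(0.75))
  if (s <= 0) stop_data("degenerate ratio distribution; null scale is 0")
  r <- x[pos]
  n_pos <- vapply(r, function(v) sum(x >= v), integer(1))
  raw <- n * pnorm(-r / s) / n_pos
  ord <- order(r)
  q[pos[ord]] <- pmin(1, cummin(raw[ord]))
  q
}

#' Empirical FDR from the ratio distribution
#'
#' Estimates a per-protein q-value from the shape of the per-time-point
#' ratio distribution, under the assumption that non-interacting proteins
#' are symmetric about the distribution center. The default mirror
#' estimator counts, for each positively centered ratio r, how many proteins
#' are at least as extreme on the negative (null) side as on the positive
#' side:
#' `raw FDR(r) = (pseudocount + #\{x_j <= -r\}) / #\{x_j >= r\}`,
#' with ties counted on both closed sides. Raw FDRs are converted to
#' q-values by taking, for each protein, the minimum raw FDR over all
#' thresholds at or below its ratio (so q-values are monotone non-increasing
#' in the ratio), clipped to `[0, 1]`. Proteins at or below the center get
#' q = 1 (screening is one-sided for enrichment in the enzyme-active
#' condition).
#'
#' The default `pseudocount = 1` is the standard finite-sample correction:
#' it prevents a raw FDR of exactly 0 from being claimed on the evidence of
#' finitely many null counts, and is what gives the screen its empirical
#' FDR control. `pseudocount = 0` gives the plain count-ratio estimator.
#'
#' @param ratios a `ratio_table` from [compute_log_ratios()].
#' @param center centering statistic for the null: `"median"` (default,
#'   robust to a planted positive tail), `"mode"` (kernel density peak), or
#'   `"none"` (ratios already centered).
#' @param null `"mirror"` (default) or `"gaussian"` (normal null with scale
#'   fitted to the central 50%).
#' @param pseudocount added to the mirror numerator (default 1).
#' @return The `ratio_table` with `qvalue` filled in.
#' @export
estimate_empirical_fdr <- function(ratios,
                                   center = c("median", "mode", "none"),
                                   null = c("mirror", "gaussian"),
                                   pseudocount = 1) {
  center <- match.arg(center)
  null <- match.arg(null)
  if (nrow(ratios) < 10)
    stop_data("need >= 10 proteins to estimate the ratio distribution")
  r <- ratios$log2fc
  c0 <- switch(center,
               median = median(r),
               mode = {
                 d <- density(r)
                 d$x[which.max(d$y)]
               },
               none = 0)
  x <- r - c0
  ratios$qvalue <- switch(null,
                          mirror = mirror_qvalues(x, pseudocount),
                          gaussian = gaussian_qvalues(x))
  attr(ratios, "center") <- c0
  ratios
}

#' Screen interacting proteins
#'
#' Applies the joint fold-change and FDR gate: a protein passes iff
#' `log2fc >= log2(fc_threshold)` and `qvalue <= fdr_threshold`. The
#' defaults (FC 1.2, FDR 0.05) are the thresholds used to call true-positive
#' nanoparticle-interacting proteins.
#'
#' @param ratios a `ratio_table` with q-values set.
#' @param fc_threshold linear fold-change threshold (> 0; default 1.2).
#' @param fdr_threshold q-value threshold (default 0.05).
#' @return Object of class `screening_result`: list with `time_min`,
#'   `table` (protein_id, log2fc, qvalue, pass), `pass_set`,
#'   `fc_threshold`, `fdr_threshold`.
#' @export
screen_interactors <- function(ratios, fc_threshold = 1.2,
                               fdr_threshold = 0.05) {
  if (fc_threshold <= 0) stop_config("fc_threshold must be > 0")
  if (anyNA(ratios$qvalue))
    stop_data("q-values unset; run estimate_empirical_fdr() first")
  tab <- as.data.frame(ratios)
  tab$pass <- tab$log2fc >= log2(fc_threshold) & tab$qvalue <= fdr_threshold
  structure(list(time_min = attr(ratios, "time_min"),
                 table = tab,
                 pass_set = tab$protein_id[tab$pass],
                 fc_threshold = fc_threshold,
                 fdr_threshold = fdr_threshold),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening_result: t = %g min, %d/%d proteins pass (FC >= %g, q <= %g)\n",
              x$time_min, length(x$pass_set), nrow(x$table),
              x$fc_threshold, x$fdr_threshold))
  invisible(x)
}

#' Convenience: screen every time point of a matrix
#'
#' @param matrix fully imputed LOG2 [lfq_matrix()].
#' @param fc_threshold,fdr_threshold gates, see [screen_interactors()].
#' @param ... passed to [estimate_empirical_fdr()].
#' @return List of `screening_result`, one per time point, in time order.
#' @export
screen_all_times <- function(matrix, fc_threshold = 1.2,
                             fdr_threshold = 0.05, ...) {
  lapply(time_points(matrix), function(tt) {
    ratios <- estimate_empirical_fdr(compute_log_ratios(matrix, tt), ...)
    screen_interactors(ratios, fc_threshold, fdr_threshold)
  })
}

#' Per-time-point dynamics of the screened set
#'
#' Counts of passing proteins per time point and the summed raw-scale LFQ
#' intensity of the passing proteins over the POS samples at that time —
#' the two global dynamics statistics (category and abundance of the
#' interacting set over the chase).
#'
#' @param screens list of `screening_result` (one per time point).
#' @param matrix the [lfq_matrix()] the screens were computed from.
#' @return data.frame with columns `time_min`, `n_pass`, `sum_lfq_pos`.
#' @export
summarize_dynamics <- function(screens, matrix) {
  times <- vapply(screens, `[[`, numeric(1), "time_min")
  if (anyDuplicated(times)) stop_data("duplicated time points in screens")
  vals <- matrix$values
  if (matrix$scale == "LOG2") vals <- 2^vals
  out <- data.frame(time_min = times, n_pass = NA_integer_,
                    sum_lfq_pos = NA_real_)
  for (i in seq_along(screens)) {
    ids <- screens[[i]]$pass_set
    out$n_pass[i] <- length(ids)
    cols <- sample_cols(matrix, "POS", times[i])
    out$sum_lfq_pos[i] <- if (length(ids))
      sum(vals[ids, cols, drop = FALSE], na.rm = TRUE) else 0
  }
  out[order(out$time_min), ]
}
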