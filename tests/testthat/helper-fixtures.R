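# Small in-code fixtures shared across tests.

# lfq_matrix from a values matrix laid out as POS then NEG blocks over the
# given time points, n_rep replicates each.
make_lfq <- function(values, time_points = c(0, 5), n_rep = 2,
                     scale = "LOG2") {
  samples <- expand.grid(replicate = seq_len(n_rep), time_min = time_points,
                         condition = c("POS", "NEG"),
                         stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "time_min", "replicate")]
  samples$sample_id <- sprintf("%s_t%g_r%d", samples$condition,
                               samples$time_min, samples$replicate)
  stopifnot(ncol(values) == nrow(samples))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  lfq_matrix(values, samples, scale = scale)
}

# one-time-point matrix with given POS / NEG replicate values per protein
make_lfq_1t <- function(pos, neg) {
  stopifnot(ncol(pos) == ncol(neg))
  make_lfq(cbind(pos, neg), time_points = 0, n_rep = ncol(pos))
}

# ratio_table wrapper around a plain vector of log2 fold changes
make_ratios <- function(log2fc, time_min = 0) {
  out <- data.frame(protein_id = sprintf("P%03d", seq_along(log2fc)),
                    log2fc = log2fc, qvalue = NA_real_)
  attr(out, "time_min") <- time_min
  class(out) <- c("ratio_table", "data.frame")
  out
}

# MaxQuant-style proteinGroups TSV fixture on disk; returns the path
write_pg_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal screening_result
make_screen <- function(time_min, pass_ids) {
  n <- length(pass_ids)
  structure(list(time_min = time_min,
                 table = data.frame(protein_id = pass_ids,
                                    log2fc = rep(1, n), qvalue = rep(0, n),
                                    pass = rep(TRUE, n)),
                 pass_set = pass_ids,
                 fc_threshold = 1.2, fdr_threshold = 0.05),
            class = "screening_result")
}

# trajectory_set from a plain matrix of z-vectors
make_trajset <- function(z, time_min = c(0, 5, 10, 20, 30, 60)) {
  if (is.null(rownames(z))) rownames(z) <- sprintf("P%03d", seq_len(nrow(z)))
  structure(list(trajectories = z, time_min = time_min,
                 degenerate = setNames(rep(FALSE, nrow(z)), rownames(z))),
            class = "trajectory_set")
}
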