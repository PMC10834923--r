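# Independent brute-force oracles. These re-derive expected values by
# direct enumeration of the definitions, without using any of the package's
# vectorized/sorted code paths.

# Mirror empirical FDR by O(n^2) double loops. `center_value` is applied
# before counting; q-values by explicit per-protein minimum over all raw
# FDRs at thresholds at or below the protein's ratio.
mirror_fdr_oracle <- function(r, center_value = stats::median(r),
                              pseudocount = 1) {
  x <- r - center_value
  n <- length(x)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (x[i] <= 0) next
    n_neg <- 0L; n_pos <- 0L
    for (j in seq_len(n)) {
      if (x[j] <= -x[i]) n_neg <- n_neg + 1L
      if (x[j] >= x[i]) n_pos <- n_pos + 1L
    }
    raw[i] <- (pseudocount + n_neg) / n_pos
  }
  q <- rep(1, n)
  for (i in seq_len(n)) {
    if (x[i] <= 0) next
    best <- Inf
    for (j in seq_len(n))
      if (!is.na(raw[j]) && x[j] <= x[i] && raw[j] < best) best <- raw[j]
    q[i] <- min(1, best)
  }
  q
}

# Region-overlap coefficients by exhaustive pixel enumeration.
region_overlap_oracle <- function(a, b, ta, tb) {
  sa <- 0; sab_a <- 0; sb <- 0; sab_b <- 0
  n_both <- 0L; n_union <- 0L; n_a <- 0L; n_b <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    in_a <- a[i, j] > ta; in_b <- b[i, j] > tb
    if (in_a) { sa <- sa + a[i, j]; n_a <- n_a + 1L }
    if (in_b) { sb <- sb + b[i, j]; n_b <- n_b + 1L }
    if (in_a && in_b) {
      sab_a <- sab_a + a[i, j]; sab_b <- sab_b + b[i, j]
      n_both <- n_both + 1L
    }
    if (in_a || in_b) n_union <- n_union + 1L
  }
  list(M1 = sab_a / sa, M2 = sab_b / sb, jaccard = n_both / n_union,
       n_a = n_a, n_b = n_b, n_both = n_both)
}

# Population z-score by the defining formula.
zscore_oracle <- function(v) {
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / length(v))
  (v - m) / s
}

# One seed of the organelle-timeline recovery experiment. Simulated at
# 2000 proteins so every organelle contributes a solid interactor set
# (mid-course time points then carry ~50 active proteins, comparable to a
# real screen's per-time discovery counts).
timeline_order_recovered <- function(seed) {
  cfg <- sim_config(n_proteins = 2000, planted_fraction = 0.1,
                    planted_log2fc = 1, noise_sd = 0.25, dropout_rate = 0,
                    seed = seed)
  ann <- generate_annotation_catalog(2000, cfg$organelle_priors, seed = seed)
  truth <- generate_truth(ann, cfg)
  mat <- generate_lfq_dataset(truth, cfg)
  screens <- screen_all_times(mat)
  ids <- unique(unlist(lapply(screens, `[[`, "pass_set")))
  if (!length(ids)) return(FALSE)
  ts <- build_trajectories(mat, ids)
  trend <- suppressWarnings(organelle_abundance_trend(ts, ann, screens))
  need <- c("EE", "ER", "LE", "Lysosome", "Golgi")
  if (!all(need %in% rownames(trend))) return(FALSE)
  tp <- as.numeric(colnames(trend))
  peak <- vapply(need, function(o) tp[which.max(trend[o, ])], numeric(1))
  w <- infer_participation_windows(trend[need, ], theta = 0.7)
  peak[["EE"]] <= 5 &&
    peak[["LE"]] %in% c(10, 20) &&
    peak[["Lysosome"]] %in% c(10, 20, 30) &&
    peak[["Golgi"]] >= 30 &&
    any(w$organelle == "ER" & w$t_start == 0) &&
    any(w$organelle == "ER" & w$t_end == 60)
}

# Closed-form simple least squares via the normal equations.
ols_oracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}
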