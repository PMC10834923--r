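#' Simulation configuration
#'
#' Parameters of the synthetic LFQ generator. Defaults emulate the study
#' design the pipeline targets: six chase times (0, 5, 10, 20, 30, 60 min),
#' two replicates per condition-time, ~1500 quantified proteins, log-normal
#' replicate noise on log2 intensities, a planted positive-condition
#' enrichment for a fraction of proteins at organelle-specific active times,
#' and intensity-dependent (missing-not-at-random) dropout.
#'
#' @param n_proteins number of proteins.
#' @param time_points_min strictly increasing chase times (minutes).
#' @param n_replicates replicates per condition-time.
#' @param baseline_log2_mean,baseline_log2_sd mean and between-protein SD of
#'   baseline log2 intensity.
#' @param noise_sd within-replicate SD on the log2 scale.
#' @param planted_fraction fraction of proteins planted as interactors.
#' @param planted_log2fc log2 fold change (>= 0) added to POS samples at an
#'   interactor's active time points.
#' @param dropout_rate overall fraction of cells dropped (0 disables
#'   dropout).
#' @param dropout_steepness slope of the logistic missing-not-at-random
#'   model, per log2 unit; larger values give a sharper detection limit.
#' @param organelle_priors named probabilities over the organelle vocabulary
#'   (must sum to 1).
#' @param multi_label_prob probability that a protein carries a second
#'   organelle label.
#' @param archetype_map named integer vector organelle -> archetype id
#'   (see [trajectory_archetypes()]).
#' @param seed integer seed; all generator functions are deterministic given
#'   the config.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1500,
                       time_points_min = DEFAULT_TIME_POINTS,
                       n_replicates = 2,
                       baseline_log2_mean = 25,
                       baseline_log2_sd = 2,
                       noise_sd = 0.25,
                       planted_fraction = 0.1,
                       planted_log2fc = 1,
                       dropout_rate = 0.1,
                       dropout_steepness = 3,
                       organelle_priors = c(EE = 0.12, LE = 0.12,
                                            Lysosome = 0.15, ER = 0.18,
                                            Golgi = 0.10,
                                            Extracellular = 0.08,
                                            Other = 0.25),
                       multi_label_prob = 0.05,
                       archetype_map = default_archetype_map(),
                       seed = 1L) {
  if (n_proteins < 1) stop_config("n_proteins must be >= 1")
  if (is.unsorted(time_points_min, strictly = TRUE))
    stop_config("time_points_min must be strictly increasing")
  if (n_replicates < 1) stop_config("n_replicates must be >= 1")
  if (abs(sum(organelle_priors) - 1) > 1e-9)
    stop_config("organelle_priors must sum to 1 (got %.6f)",
                sum(organelle_priors))
  if (!all(names(organelle_priors) %in% ORGANELLE_LEVELS))
    stop_config("organelle_priors names must be in the controlled vocabulary")
  if (planted_fraction < 0 || planted_fraction > 1)
    stop_config("planted_fraction must be in [0, 1]")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop_config("dropout_rate must be in [0, 1]")
  if (planted_log2fc < 0) stop_config("planted_log2fc must be >= 0")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(list(n_proteins = as.integer(n_proteins),
                 time_points_min = time_points_min,
                 n_replicates = as.integer(n_replicates),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_sd = noise_sd,
                 planted_fraction = planted_fraction,
                 planted_log2fc = planted_log2fc,
                 dropout_rate = dropout_rate,
                 dropout_steepness = dropout_steepness,
                 organelle_priors = organelle_priors,
                 multi_label_prob = multi_label_prob,
                 archetype_map = archetype_map,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic protein-to-organelle catalog
#'
#' Draws one primary organelle label per protein from `organelle_priors`
#' (plus, with probability `multi_label_prob`, a second label) and an enzyme
#' flag (more likely for lysosomal proteins).
#'
#' @param n_proteins number of proteins.
#' @param organelle_priors named probabilities summing to 1.
#' @param seed integer seed.
#' @param multi_label_prob probability of a second label.
#' @return An [annotation_table()] with an extra attribute
#'   `"primary_organelle"` (character vector) used to assign archetypes.
#' @export
generate_annotation_catalog <- function(n_proteins, organelle_priors,
                                        seed = 1L, multi_label_prob = 0.05) {
  if (abs(sum(organelle_priors) - 1) > 1e-9)
    stop_config("organelle_priors must sum to 1")
  if (n_proteins < 1) stop_config("n_proteins must be >= 1")
  withr::with_seed(seed, {
    orgs <- names(organelle_priors)
    primary <- sample(orgs, n_proteins, replace = TRUE,
                      prob = organelle_priors)
    labels <- as.list(primary)
    if (length(orgs) > 1 && multi_label_prob > 0) {
      extra <- runif(n_proteins) < multi_label_prob
      for (i in which(extra)) {
        rest <- setdiff(orgs, primary[i])
        p <- organelle_priors[rest] / sum(organelle_priors[rest])
        labels[[i]] <- c(primary[i], sample(rest, 1, prob = p))
      }
    }
    enzyme <- runif(n_proteins) <
      ifelse(vapply(labels, function(l) "Lysosome" %in% l, TRUE), 0.25, 0.10)
    ids <- sprintf("P%05d", seq_len(n_proteins))
    ann <- annotation_table(ids, labels, enzyme)
    attr(ann, "primary_organelle") <- primary
    ann
  })
}

#' Generate planted ground truth
#'
#' Marks each protein as interactor with probability `planted_fraction`;
#' interactors receive the trajectory archetype mapped from their primary
#' organelle, active time points from [archetype_active_times()], and a
#' per-active-time effect of `planted_log2fc` log2 units. Non-interactors
#' have no active times.
#'
#' @param catalog output of [generate_annotation_catalog()].
#' @param config a [sim_config()].
#' @return Object of class `planted_truth`: data.frame with columns
#'   `protein_id`, `organelle` (primary), `is_interactor`, `archetype_id`,
#'   and list column `active_times`.
#' @export
generate_truth <- function(catalog, config) {
  if (nrow(catalog) == 0) stop_data("catalog is empty")
  primary <- attr(catalog, "primary_organelle") %||%
    vapply(catalog$labels, `[`, character(1), 1)
  missing_org <- setdiff(unique(primary), names(config$archetype_map))
  if (length(missing_org))
    stop_config("archetype_map missing organelle(s): %s",
                paste(missing_org, collapse = ", "))
  withr::with_seed(config$seed + 1L, {
    n <- nrow(catalog)
    is_int <- runif(n) < config$planted_fraction
    arch <- ifelse(is_int, config$archetype_map[primary], NA_integer_)
    act <- vector("list", n)
    for (i in seq_len(n)) {
      act[[i]] <- if (is_int[i])
        archetype_active_times(arch[i],
                               time_points_min = config$time_points_min)
      else numeric(0)
    }
    df <- data.frame(protein_id = catalog$protein_id,
                     organelle = primary,
                     is_interactor = is_int,
                     archetype_id = as.integer(arch))
    df$active_times <- act
    df$effect_log2fc <- ifelse(is_int, config$planted_log2fc, 0)
    class(df) <- c("planted_truth", "data.frame")
    df
  })
}

# Solve the logistic MNAR offset so the expected missing fraction over the
# realized true values equals `rate`.
solve_dropout_offset <- function(values, rate, steepness) {
  f <- function(x0) mean(plogis(-steepness * (values - x0))) - rate
  lo <- min(values) - 60 / steepness
  hi <- max(values) + 60 / steepness
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate a synthetic LFQ dataset
#'
#' Log2 intensity of protein i in sample (condition, time, replicate) is
#' `baseline_i + [condition == POS and time active for i] * effect +
#' N(0, noise_sd^2)`. Cells are then dropped missing-not-at-random with
#' logistic probability decreasing in the true intensity, the offset solved
#' numerically so the realized overall missing fraction matches
#' `dropout_rate` in expectation.
#'
#' @param truth output of [generate_truth()].
#' @param config a [sim_config()].
#' @return An [lfq_matrix()] on the LOG2 scale.
#' @export
generate_lfq_dataset <- function(truth, config) {
  if (nrow(truth) != config$n_proteins)
    stop_config("truth has %d proteins but config specifies %d",
                nrow(truth), config$n_proteins)
  tps <- config$time_points_min
  nrep <- config$n_replicates
  samples <- expand.grid(replicate = seq_len(nrep), time_min = tps,
                         condition = c("POS", "NEG"),
                         stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "time_min", "replicate")]
  samples$sample_id <- sprintf("%s_t%g_r%d", samples$condition,
                               samples$time_min, samples$replicate)
  n <- nrow(truth)
  withr::with_seed(config$seed + 2L, {
    baseline <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    active <- vapply(tps, function(t)
      vapply(truth$active_times, function(a) t %in% a, TRUE), logical(n))
    vals <- matrix(NA_real_, n, nrow(samples),
                   dimnames = list(truth$protein_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      ti <- match(samples$time_min[j], tps)
      eff <- if (samples$condition[j] == "POS")
        active[, ti] * truth$effect_log2fc else 0
      vals[, j] <- baseline + eff + rnorm(n, 0, config$noise_sd)
    }
    if (config$dropout_rate > 0) {
      x0 <- solve_dropout_offset(as.vector(vals), config$dropout_rate,
                                 config$dropout_steepness)
      p_miss <- plogis(-config$dropout_steepness * (vals - x0))
      vals[matrix(runif(length(vals)), n) < p_miss] <- NA
    }
    lfq_matrix(vals, samples, scale = "LOG2")
  })
}

#' Simulate archetype-shaped trajectories
#'
#' Draws `n_per_archetype` six-point trajectories per archetype as the
#' z-normalized template plus i.i.d. Gaussian noise of SD `noise_sd` per
#' coordinate. Used to exercise trajectory clustering against known shape
#' ground truth.
#'
#' @param n_per_archetype proteins per archetype.
#' @param noise_sd per-coordinate noise SD.
#' @param seed integer seed.
#' @param archetype_ids which archetypes to include (default all ten).
#' @return List with `trajectories` (matrix), `archetype` (integer vector of
#'   true archetype per row), `templates` (z-normalized template matrix).
#' @export
simulate_archetype_trajectories <- function(n_per_archetype = 100,
                                            noise_sd = 0.1, seed = 1L,
                                            archetype_ids = 1:10) {
  tmpl <- trajectory_archetypes()
  ztmpl <- t(apply(tmpl[archetype_ids, , drop = FALSE], 1, function(v)
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))))
  withr::with_seed(seed, {
    k <- length(archetype_ids)
    traj <- ztmpl[rep(seq_len(k), each = n_per_archetype), , drop = FALSE] +
      matrix(rnorm(k * n_per_archetype * ncol(ztmpl), 0, noise_sd),
             k * n_per_archetype)
    rownames(traj) <- sprintf("T%05d", seq_len(nrow(traj)))
    list(trajectories = traj,
         archetype = rep(archetype_ids, each = n_per_archetype),
         templates = ztmpl)
  })
}

#' Generate a correlated two-channel image pair
#'
#' Produces two non-negative single-channel images whose pixelwise Pearson
#' correlation equals `correlation_target` up to sampling error of order
#' `1/sqrt(n_pixels)`; for targets of exactly +/-1 the second channel is an
#' exact affine transform of the first.
#'
#' @param correlation_target value in `[-1, 1]`.
#' @param shape integer vector `c(rows, cols)`.
#' @param seed integer seed.
#' @return An [image_pair()].
#' @export
generate_coloc_images <- function(correlation_target, shape = c(64, 64),
                                  seed = 1L) {
  if (abs(correlation_target) > 1)
    stop_config("correlation_target must be in [-1, 1]")
  if (prod(shape) < 2) stop_config("image must have at least 2 pixels")
  withr::with_seed(seed, {
    n <- prod(shape)
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    rho <- correlation_target
    y <- rho * z1 + sqrt(max(0, 1 - rho^2)) * z2
    a <- matrix(z1 - min(z1), shape[1], shape[2])
    b <- matrix(y - min(y), shape[1], shape[2])
    image_pair(a, b)
  })
}

#' Write a synthetic LFQ dataset as a protein-groups TSV
#'
#' Emits the MaxQuant-style dialect consumed by [read_protein_groups()]:
#' a `Protein IDs` column, one `LFQ intensity <sample_id>` column per sample
#' (linear scale; missing cells written as 0), and empty `Reverse` /
#' `Potential contaminant` columns.
#'
#' @param matrix an [lfq_matrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_lfq_tsv <- function(matrix, path) {
  vals <- matrix$values
  if (matrix$scale == "LOG2") vals <- 2^vals
  vals[is.na(vals)] <- 0
  df <- data.frame(`Protein IDs` = rownames(vals), check.names = FALSE)
  for (j in seq_len(ncol(vals)))
    df[[paste("LFQ intensity", colnames(vals)[j])]] <- vals[, j]
  df$Reverse <- ""
  df$`Potential contaminant` <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write planted ground truth as TSV
#' @param truth a `planted_truth` data.frame.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- data.frame(protein_id = truth$protein_id,
                   organelle = truth$organelle,
                   is_interactor = truth$is_interactor,
                   archetype_id = truth$archetype_id,
                   active_times = vapply(truth$active_times, paste,
                                         character(1), collapse = ","),
                   effect_log2fc = truth$effect_log2fc)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
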