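#' Pipeline configuration
#'
#' Bundles all stage parameters with either a simulation config or input
#' file paths. Defaults are the analysis' canonical settings: FC threshold
#' 1.2, FDR 0.05, k = 10 clusters, window threshold 0.7.
#'
#' @param simulate a [sim_config()], or `NULL` when reading files.
#' @param proteins_path,annotations_path input TSVs (used when `simulate`
#'   is `NULL`).
#' @param min_valid_per_group valid-value filter threshold.
#' @param impute_width,impute_downshift imputation parameters.
#' @param median_center apply between-sample median centering (default
#'   `FALSE`; LFQ intensities are assumed pre-normalized upstream).
#' @param fc_threshold,fdr_threshold screening gates.
#' @param fdr_null,fdr_center,fdr_pseudocount FDR estimator options, see
#'   [estimate_empirical_fdr()].
#' @param k,n_init,cluster_method clustering options.
#' @param theta participation-window threshold.
#' @param seed integer master seed, split deterministically into per-stage
#'   substreams.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL,
                            proteins_path = NULL, annotations_path = NULL,
                            min_valid_per_group = 1,
                            impute_width = 0.3, impute_downshift = 1.8,
                            median_center = FALSE,
                            fc_threshold = 1.2, fdr_threshold = 0.05,
                            fdr_null = "mirror", fdr_center = "median",
                            fdr_pseudocount = 1,
                            k = 10, n_init = 50, cluster_method = "kmeans",
                            theta = 0.7, seed = 1L) {
  if (is.null(simulate) && (is.null(proteins_path) || is.null(annotations_path)))
    stop_config("provide either a simulation config or input file paths")
  if (!is.null(simulate) && !inherits(simulate, "sim_config"))
    stop_config("`simulate` must be a sim_config")
  structure(as.list(environment()), class = "pipeline_config")
}

# Deterministic per-stage substreams from the master seed.
stage_seeds <- function(seed) {
  withr::with_seed(seed,
    setNames(sample.int(.Machine$integer.max - 1L, 3),
             c("simulate", "impute", "cluster")))
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> log-transform -> QC -> filter -> impute -> screen
#' per time point -> dynamics summary -> trajectories -> clustering ->
#' organelle timeline. Fully deterministic given the config (one master
#' seed split into per-stage substreams).
#'
#' @param config a [pipeline_config()].
#' @return Object of class `report_bundle`: list with elements `config`,
#'   `qc` (replicate correlations, missingness), `screens`, `dynamics`,
#'   `trajectories`, `clusters`, `composition`, `timeline`, and (when
#'   simulated) `truth`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_config("config must be a pipeline_config")
  seeds <- stage_seeds(config$seed)

  if (!is.null(config$simulate)) {
    sc <- config$simulate
    sc$seed <- seeds[["simulate"]]
    catalog <- generate_annotation_catalog(sc$n_proteins, sc$organelle_priors,
                                           seed = sc$seed,
                                           multi_label_prob = sc$multi_label_prob)
    truth <- generate_truth(catalog, sc)
    mat <- generate_lfq_dataset(truth, sc)
    annotations <- catalog
  } else {
    mat <- log_transform(read_protein_groups(config$proteins_path))
    annotations <- read_annotations(config$annotations_path)
    truth <- NULL
  }

  qc <- list(replicate_correlation = replicate_correlation(mat),
             missing_fraction = missing_fraction(mat))

  mat <- filter_valid_values(mat, config$min_valid_per_group)
  if (config$median_center) mat <- median_center(mat)
  mat <- impute_downshifted(mat, config$impute_width,
                            config$impute_downshift,
                            seed = seeds[["impute"]])

  screens <- screen_all_times(mat, config$fc_threshold, config$fdr_threshold,
                              center = config$fdr_center,
                              null = config$fdr_null,
                              pseudocount = config$fdr_pseudocount)
  dynamics <- summarize_dynamics(screens, mat)

  union_ids <- unique(unlist(lapply(screens, `[[`, "pass_set")))
  trajectories <- clusters <- composition <- timeline <- NULL
  if (length(union_ids)) {
    trajectories <- build_trajectories(mat, union_ids)
    n_distinct <- nrow(unique(
      trajectories$trajectories[!trajectories$degenerate, , drop = FALSE]))
    if (n_distinct >= config$k) {
      clusters <- cluster_trajectories(trajectories, k = config$k,
                                       seed = seeds[["cluster"]],
                                       n_init = config$n_init,
                                       method = config$cluster_method)
      composition <- cluster_organelle_composition(clusters, annotations)
    }
    timeline <- timeline_report(screens, trajectories, annotations,
                                config$theta)
  }

  structure(list(config = config, qc = qc, screens = screens,
                 dynamics = dynamics, trajectories = trajectories,
                 clusters = clusters, composition = composition,
                 timeline = timeline, truth = truth),
            class = "report_bundle")
}

# Serialize a config to a canonical JSON string (for hashing).
config_json <- function(config) {
  x <- unclass(config)
  x$simulate <- if (!is.null(x$simulate)) unclass(x$simulate)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

md5_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

#' Write a report bundle to disk
#'
#' Emits one CSV per screened time point, the dynamics summary, cluster
#' assignment/centroids/composition, the organelle timeline (CSV + JSON),
#' QC tables and, for simulated runs, the planted truth; plus a
#' `manifest.json` listing every file with its MD5, the config hash and the
#' seed. Outputs are deterministic: rerunning the same bundle reproduces
#' identical files.
#'
#' @param bundle a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop_data("cannot write to %s", out_dir)
  files <- character(0)
  put_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  for (s in bundle$screens %||% list())
    put_csv(s$table, sprintf("screen_t%g.csv", s$time_min))
  if (!is.null(bundle$dynamics)) put_csv(bundle$dynamics, "dynamics.csv")
  if (!is.null(bundle$qc)) {
    put_csv(bundle$qc$replicate_correlation, "qc_replicate_correlation.csv")
    put_csv(data.frame(missing_fraction = bundle$qc$missing_fraction),
            "qc_missingness.csv")
  }
  if (!is.null(bundle$clusters)) {
    put_csv(bundle$clusters$assignment, "clusters.csv")
    put_csv(data.frame(cluster_id = rownames(bundle$clusters$centroids),
                       bundle$clusters$centroids, check.names = FALSE),
            "centroids.csv")
    put_csv(bundle$composition, "composition.csv")
  }
  if (!is.null(bundle$timeline)) {
    put_csv(data.frame(organelle = rownames(bundle$timeline$counts),
                       bundle$timeline$counts, check.names = FALSE),
            "organelle_counts.csv")
    put_csv(data.frame(organelle = rownames(bundle$timeline$trend),
                       bundle$timeline$trend, check.names = FALSE),
            "organelle_trend.csv")
    put_csv(as.data.frame(bundle$timeline$windows), "windows.csv")
    tl <- list(theta = bundle$timeline$theta,
               counts = as.data.frame(bundle$timeline$counts),
               trend = as.data.frame(bundle$timeline$trend),
               windows = as.data.frame(bundle$timeline$windows))
    jsonlite::write_json(tl, file.path(out_dir, "timeline.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "timeline.json")
  }
  if (!is.null(bundle$truth)) {
    write_truth_tsv(bundle$truth, file.path(out_dir, "truth.tsv"))
    files <- c(files, "truth.tsv")
  }
  manifest <- list(
    config_hash = md5_string(config_json(bundle$config)),
    seed = bundle$config$seed,
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
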