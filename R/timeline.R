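#' Organelle protein counts over time
#'
#' For every organelle label and time point, the number of passing proteins
#' at that time carrying the label. Multi-label proteins are counted once
#' per label, so column sums can exceed the size of the pass set.
#'
#' @param screens list of `screening_result` (one per time point).
#' @param annotations an [annotation_table()] covering all passing proteins.
#' @return Integer matrix, organelles x time points.
#' @export
organelle_counts_over_time <- function(screens, annotations) {
  times <- sort(vapply(screens, `[[`, numeric(1), "time_min"))
  orgs <- ORGANELLE_LEVELS
  counts <- matrix(0L, length(orgs), length(times),
                   dimnames = list(orgs, times))
  for (s in screens) {
    ids <- s$pass_set
    if (!length(ids)) next
    labs <- annotation_labels(annotations, ids, "passing protein")
    tb <- table(factor(unlist(labs), levels = orgs))
    counts[, as.character(s$time_min)] <- as.integer(tb)
  }
  counts
}

#' Mean organelle abundance trend
#'
#' For each organelle, the mean z-normalized trajectory over the screened
#' union of proteins carrying the label — the relative-abundance view of
#' when each organelle's interacting proteins are high. Organelles with no
#' screened proteins are omitted with a warning.
#'
#' @param trajset a [build_trajectories()] result covering the screened
#'   union.
#' @param annotations an [annotation_table()].
#' @param screens list of `screening_result`; the union of their pass sets
#'   defines the protein set.
#' @return Numeric matrix, organelles x time points; attribute `n_proteins`
#'   gives per-organelle protein counts.
#' @export
organelle_abundance_trend <- function(trajset, annotations, screens) {
  ids <- unique(unlist(lapply(screens, `[[`, "pass_set")))
  ids <- intersect(rownames(trajset$trajectories), ids)
  if (!length(ids)) stop_data("no screened proteins with trajectories")
  labs <- annotation_labels(annotations, ids, "screened protein")
  orgs <- ORGANELLE_LEVELS
  rows <- list(); nprot <- integer(0)
  for (org in orgs) {
    members <- ids[vapply(labs, function(l) org %in% l, TRUE)]
    if (!length(members)) next
    rows[[org]] <- colMeans(trajset$trajectories[members, , drop = FALSE])
    nprot[org] <- length(members)
  }
  omitted <- setdiff(orgs, names(rows))
  if (length(omitted))
    warning(sprintf("no screened proteins for organelle(s): %s",
                    paste(omitted, collapse = ", ")), call. = FALSE)
  trend <- do.call(rbind, rows)
  colnames(trend) <- trajset$time_min
  attr(trend, "n_proteins") <- nprot
  trend
}

#' Infer organelle participation windows
#'
#' Formalizes the organelle timeline: each organelle's trend is min-max
#' rescaled to `[0, 1]` and its participation windows are the maximal runs
#' of consecutive time points with rescaled value at least `theta`. The rule
#' is invariant under positive affine rescaling of the trend. A constant
#' trend cannot be rescaled; it yields a single window spanning the whole
#' course, flagged degenerate.
#'
#' @param trend organelles x time points matrix (e.g. from
#'   [organelle_abundance_trend()]); column names are times in minutes.
#' @param theta window threshold fraction in (0, 1], default 0.7.
#' @return Object of class `timeline_report`: data.frame with one row per
#'   window (`organelle`, `t_start`, `t_end`, `degenerate`); attribute
#'   `theta`.
#' @export
infer_participation_windows <- function(trend, theta = 0.7) {
  if (theta <= 0 || theta > 1) stop_config("theta must be in (0, 1]")
  if (any(!is.finite(trend))) stop_data("trend values must be finite")
  tps <- as.numeric(colnames(trend))
  out <- list()
  for (org in rownames(trend)) {
    v <- trend[org, ]
    rng <- max(v) - min(v)
    if (rng < 1e-12) {
      out[[length(out) + 1L]] <- data.frame(
        organelle = org, t_start = tps[1], t_end = tps[length(tps)],
        degenerate = TRUE)
      next
    }
    high <- (v - min(v)) / rng >= theta
    r <- rle(high)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        organelle = org, t_start = tps[starts[i]], t_end = tps[ends[i]],
        degenerate = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "theta") <- theta
  class(res) <- c("timeline_report", "data.frame")
  res
}

#' Assemble the full organelle timeline report
#'
#' Convenience wrapper producing counts, trends and participation windows
#' in one structure.
#'
#' @param screens list of `screening_result`.
#' @param trajset a [build_trajectories()] result for the screened union.
#' @param annotations an [annotation_table()].
#' @param theta window threshold, see [infer_participation_windows()].
#' @return List with `counts`, `trend`, `windows`, `theta`.
#' @export
timeline_report <- function(screens, trajset, annotations, theta = 0.7) {
  counts <- organelle_counts_over_time(screens, annotations)
  trend <- organelle_abundance_trend(trajset, annotations, screens)
  windows <- infer_participation_windows(trend, theta)
  list(counts = counts, trend = trend, windows = windows, theta = theta)
}
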