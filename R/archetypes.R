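#' Trajectory archetype library
#'
#' Ten piecewise-linear template shapes over the six-point chase time course
#' (0, 5, 10, 20, 30, 60 min), chosen to span the qualitative trajectory
#' classes seen in time-resolved uptake interactomes: early peaks, mid-course
#' peaks, late rises, V-shapes and zigzags. The values are documented
#' constants on a 0-1 scale; downstream they are used (a) to define each
#' archetype's *active times* — the time points where the min-max-rescaled
#' template is at least `theta` (default 0.7, the same threshold used for
#' participation-window inference) — and (b) as cluster-shape ground truth
#' for trajectory-clustering tests.
#'
#' @param time_points_min time grid in minutes (must have length 6 for the
#'   built-in templates).
#' @return Numeric matrix `10 x 6`, rownames `A1`..`A10`, colnames the time
#'   points.
#' @export
trajectory_archetypes <- function(time_points_min = DEFAULT_TIME_POINTS) {
  if (length(time_points_min) != 6)
    stop_config("built-in archetype templates are defined on 6 time points")
  tmpl <- rbind(
    A1  = c(1.00, 0.85, 0.40, 0.20, 0.10, 0.05), # early peak
    A2  = c(1.00, 0.85, 0.30, 0.25, 0.80, 1.00), # early + late (V, two windows)
    A3  = c(0.15, 0.60, 1.00, 0.85, 0.45, 0.15), # mid peak, early-leaning
    A4  = c(0.10, 0.30, 0.75, 1.00, 0.80, 0.30), # mid plateau
    A5  = c(0.05, 0.10, 0.30, 0.60, 0.85, 1.00), # late rise
    A6  = c(0.10, 0.15, 0.40, 0.80, 1.00, 0.95), # late plateau
    A7  = c(1.00, 0.90, 0.60, 0.20, 0.50, 0.90), # V shape
    A8  = c(1.00, 0.80, 0.55, 0.35, 0.20, 0.05), # monotone decline
    A9  = c(0.10, 0.25, 0.40, 0.60, 0.80, 1.00), # monotone rise
    A10 = c(0.90, 0.40, 0.20, 0.60, 1.00, 0.50)  # zigzag
  )
  colnames(tmpl) <- time_points_min
  tmpl
}

#' Active time points of an archetype
#'
#' The time points at which the min-max-rescaled template value is at least
#' `theta`. These are the times at which proteins following the archetype
#' carry the planted enrichment in the synthetic generator.
#'
#' @param archetype_id integer in 1..10.
#' @param theta fraction in (0, 1]; default 0.7.
#' @param time_points_min time grid in minutes.
#' @return Numeric vector of active time points (minutes).
#' @export
archetype_active_times <- function(archetype_id, theta = 0.7,
                                   time_points_min = DEFAULT_TIME_POINTS) {
  tmpl <- trajectory_archetypes(time_points_min)
  if (archetype_id < 1 || archetype_id > nrow(tmpl))
    stop_config("archetype_id must be in 1..%d", nrow(tmpl))
  v <- tmpl[archetype_id, ]
  r <- (v - min(v)) / (max(v) - min(v))
  time_points_min[r >= theta]
}

#' Default organelle-to-archetype assignment
#'
#' Encodes the organelle participation timeline the generator plants: ER and
#' early endosomes engage in the initial stage, late endosomes and lysosomes
#' mid-course, the Golgi late, with the ER returning late (its archetype has
#' two active windows).
#'
#' @return Named integer vector, organelle label -> archetype id.
#' @export
default_archetype_map <- function() {
  c(EE = 1L, ER = 2L, LE = 3L, Lysosome = 4L, Golgi = 5L,
    Extracellular = 8L, Other = 10L)
}
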