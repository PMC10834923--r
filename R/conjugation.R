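#' Fit an enzyme-activity standard curve
#'
#' Ordinary least-squares line through guaiacol-assay calibration points:
#' initial absorbance change rate at 470 nm (dA470/min) against HRP
#' concentration (ug/mL).
#'
#' @param concentrations HRP concentrations (ug/mL), >= 3 distinct points.
#' @param rates corresponding dA470/min values.
#' @return Object of class `activity_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `range` (calibration concentration range).
#' @export
fit_activity_standard_curve <- function(concentrations, rates) {
  if (length(concentrations) != length(rates))
    stop_data("concentrations and rates differ in length")
  if (length(concentrations) < 3)
    stop_data("need >= 3 calibration points")
  if (sd(concentrations) == 0)
    stop_data("zero variance in calibration concentrations")
  fit <- lm(rates ~ concentrations)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((rates - mean(rates))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 range = range(concentrations)),
            class = "activity_curve")
}

#' Convert an activity rate to effective HRP concentration
#'
#' Inverts the standard curve: `(rate - intercept) / slope`. Rates mapping
#' outside the calibration range are flagged with a warning.
#'
#' @param rate measured dA470/min.
#' @param curve an [fit_activity_standard_curve()] result.
#' @return Effective HRP concentration (ug/mL).
#' @export
activity_to_hrp_mass <- function(rate, curve) {
  if (curve$slope <= 0) stop_data("invalid curve: slope must be > 0")
  if (rate < curve$intercept)
    stop_data("rate below curve intercept; concentration would be negative")
  conc <- (rate - curve$intercept) / curve$slope
  tol <- 1e-9 * max(1, abs(curve$range[2]))
  if (conc > 0 && (conc < curve$range[1] - tol || conc > curve$range[2] + tol))
    warning(sprintf("concentration %.4g ug/mL outside calibration range [%g, %g]",
                    conc, curve$range[1], curve$range[2]), call. = FALSE)
  conc
}

#' Nanoparticle specification
#'
#' Geometry and composition needed to count particles per volume: particle
#' diameter, polymer matrix density, matrix mass concentration of the
#' suspension, and the enzyme molar mass.
#'
#' @param diameter_nm particle diameter (nm).
#' @param matrix_density_g_cm3 polymer matrix density (g/cm^3).
#' @param matrix_mg_ml matrix mass concentration of the suspension (mg/mL).
#' @param hrp_molar_mass enzyme molar mass (g/mol), default 44000 for HRP.
#' @return Object of class `particle_spec`.
#' @export
particle_spec <- function(diameter_nm, matrix_density_g_cm3, matrix_mg_ml,
                          hrp_molar_mass = 44000) {
  vals <- c(diameter_nm, matrix_density_g_cm3, matrix_mg_ml, hrp_molar_mass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_config("all particle-spec fields must be strictly positive")
  structure(list(diameter_nm = diameter_nm,
                 matrix_density_g_cm3 = matrix_density_g_cm3,
                 matrix_mg_ml = matrix_mg_ml,
                 hrp_molar_mass = hrp_molar_mass),
            class = "particle_spec")
}

AVOGADRO <- 6.02214076e23

#' Enzyme molecules per nanoparticle
#'
#' Combines the surface-enzyme concentration measured by the activity assay
#' with particle geometry: particles/mL follow from the matrix mass
#' concentration divided by the mass of one sphere
#' (`density * pi/6 * diameter^3`), enzyme molecules/mL from the enzyme mass
#' concentration, molar mass and the Avogadro constant; the ratio is the
#' mean number of enzyme molecules per particle. Scales linearly in the
#' enzyme concentration; the particle count scales as diameter^-3, so the
#' per-particle load scales as diameter^3 (fewer, larger particles share
#' the same enzyme pool).
#'
#' @param hrp_ug_ml effective enzyme concentration (ug/mL).
#' @param spec a [particle_spec()].
#' @return Mean enzyme molecules per particle.
#' @export
hrp_per_particle <- function(hrp_ug_ml, spec) {
  if (!inherits(spec, "particle_spec")) stop_config("spec must be a particle_spec")
  if (hrp_ug_ml < 0) stop_config("hrp_ug_ml must be >= 0")
  d_cm <- spec$diameter_nm * 1e-7
  particle_mass_g <- spec$matrix_density_g_cm3 * pi / 6 * d_cm^3
  particles_per_ml <- (spec$matrix_mg_ml * 1e-3) / particle_mass_g
  hrp_molecules_per_ml <- (hrp_ug_ml * 1e-6) / spec$hrp_molar_mass * AVOGADRO
  hrp_molecules_per_ml / particles_per_ml
}
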