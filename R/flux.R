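# Diffusive flux from wind-based gas transfer and ebullition from funnel
# traps. Units are chosen so that uM x m d-1 gives mmol m-2 d-1 directly.

#' Gas transfer velocity at Schmidt number 600 from wind speed
#'
#' Wind-based model for low-turbulence lakes:
#' k600 = 2.07 + 0.215 * U10^1.7 (cm h-1). Used as a first approximation on
#' small sheltered ponds, where it is subsequently rescaled by a
#' chamber-derived correction factor (see [diffusive_flux()]).
#'
#' @param u10 Wind speed at 10 m, m s-1; must be >= 0.
#' @return k600, cm h-1.
#' @examples
#' k600_cole(0)   # 2.07
#' k600_cole(5)
#' @export
k600_cole <- function(u10) {
  if (any(!is.finite(u10)) || any(u10 < 0)) {
    stop("u10 must be >= 0 m s-1", call. = FALSE)
  }
  2.07 + 0.215 * u10^1.7
}

#' Mean wind speed over the window preceding a sampling instant
#'
#' Arithmetic mean of `u10_ms` over `[at - window_h, at]`. The default 2 h
#' window is the averaging period used to pair discrete gas samples with the
#' wind record.
#'
#' @param wind data.frame with `timestamp` (POSIXct) and `u10_ms`.
#' @param at Sampling instant (POSIXct, or string parseable as UTC).
#' @param window_h Window length, hours.
#' @return Mean u10, m s-1.
#' @export
wind_window_mean <- function(wind, at, window_h = 2) {
  if (!inherits(at, "POSIXct")) at <- as.POSIXct(at, tz = "UTC")
  lo <- at - window_h * 3600
  inside <- wind$timestamp >= lo & wind$timestamp <= at
  if (!any(inside)) {
    stop("no wind observations in [", format(lo, usetz = TRUE), ", ",
         format(at, usetz = TRUE), "]", call. = FALSE)
  }
  mean(wind$u10_ms[inside])
}

#' Gas transfer velocity for a given gas and temperature
#'
#' Rescales k600 to the gas of interest through the Schmidt number,
#' k = k600 * (Sc/600)^(-n), with the low-wind exponent convention:
#' n = 2/3 for U10 < 3 m s-1 and n = 1/2 at or above 3 m s-1 (the boundary
#' itself uses 1/2). Converted from cm h-1 to m d-1 (x 0.24).
#'
#' @param k600 Transfer velocity at Sc = 600, cm h-1.
#' @param schmidt Schmidt number; must be > 0.
#' @param u10 Wind speed used to select the exponent, m s-1.
#' @return k, m d-1.
#' @export
transfer_velocity <- function(k600, schmidt, u10) {
  if (any(schmidt <= 0)) stop("schmidt must be > 0", call. = FALSE)
  n <- ifelse(u10 < 3, 2 / 3, 1 / 2)
  k600 * (schmidt / 600)^(-n) * 0.24
}

#' Dissolved concentration in equilibrium with the atmosphere
#'
#' C_eq = KH(T) * x_atm * P, in uM, using the species' configured atmospheric
#' mixing ratio (ppm). Colder water holds more gas at equilibrium.
#'
#' @inheritParams henry_constant
#' @param pressure_atm Total pressure, atm.
#' @param mixing_ratio_ppm Override of the species' atmospheric mixing ratio.
#' @return Equilibrium concentration, uM.
#' @export
equilibrium_concentration <- function(species, temperature, pressure_atm = 1,
                                      mixing_ratio_ppm = species$atm_mixing_ratio) {
  dissolved_at_partial_pressure(species, temperature,
                                mixing_ratio_ppm * 1e-6 * pressure_atm)
}

#' Diffusive air-water gas flux
#'
#' F_d = correction * k * (C_sur - C_eq), in mmol m-2 d-1 when k is in m d-1
#' and concentrations in uM. The correction factor (default 0.2458) rescales
#' the wind-based k for small sheltered ponds where daytime thermal
#' stratification suppresses gas transfer; it was derived from simultaneous
#' floating-chamber CO2 fluxes (see [fit_correction_factor()]). Positive
#' flux is emission to the atmosphere; undersaturated water (C_sur < C_eq)
#' gives a negative flux, i.e. the pond is a sink.
#'
#' @param species Species constants list (recorded in the result).
#' @param c_surface Surface-water concentration, uM.
#' @param c_equilibrium Atmospheric-equilibrium concentration, uM.
#' @param k Gas transfer velocity, m d-1; must be > 0.
#' @param correction Multiplicative correction factor; must be > 0.
#' @param k600,schmidt Optional provenance values stored in the result.
#' @return data.frame with `species`, `flux_mmol_m2_d`, `k600_cm_h`,
#'   `k_m_d`, `schmidt`, `c_surface_uM`, `c_equilibrium_uM`,
#'   `correction_applied`.
#' @export
diffusive_flux <- function(species, c_surface, c_equilibrium, k,
                           correction = 0.2458, k600 = NA_real_,
                           schmidt = NA_real_) {
  if (any(k <= 0)) stop("k must be > 0 m d-1", call. = FALSE)
  if (any(correction <= 0)) stop("correction must be > 0", call. = FALSE)
  data.frame(
    species = species$name,
    flux_mmol_m2_d = correction * k * (c_surface - c_equilibrium),
    k600_cm_h = k600,
    k_m_d = k,
    schmidt = schmidt,
    c_surface_uM = c_surface,
    c_equilibrium_uM = c_equilibrium,
    correction_applied = correction
  )
}

#' Ebullition flux from a funnel collection
#'
#' F_e = (V * f_CH4) / (A * MV * t): gas volume accumulated in a submerged
#' funnel, scaled by its CH4 volume fraction, divided by funnel area, the
#' ideal-gas molar volume at ambient air temperature, and the collection
#' duration in days. Default funnel area 0.3526 m2.
#'
#' @param volume_mL Gas volume collected, mL; >= 0.
#' @param duration_h Collection duration, hours; > 0.
#' @param ch4_fraction CH4 volume fraction in the bubbles, in [0, 1].
#' @param air_temp_C Ambient air temperature, degC.
#' @param funnel_area_m2 Funnel mouth area, m2.
#' @param pressure_atm Pressure, atm.
#' @return CH4 flux, mmol m-2 d-1.
#' @examples
#' ebullition_flux(10, 24, 1, air_temp_C = 10)  # about 1.22
#' @export
ebullition_flux <- function(volume_mL, duration_h, ch4_fraction, air_temp_C,
                            funnel_area_m2 = 0.3526, pressure_atm = 1) {
  if (any(volume_mL < 0)) stop("volume_mL must be >= 0", call. = FALSE)
  if (any(duration_h <= 0)) stop("duration_h must be > 0", call. = FALSE)
  if (any(ch4_fraction < 0) || any(ch4_fraction > 1)) {
    stop("ch4_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(funnel_area_m2 <= 0)) stop("funnel_area_m2 must be > 0", call. = FALSE)
  mv <- molar_volume(air_temp_C, pressure_atm)          # L mol-1
  mol <- (volume_mL / 1000) * ch4_fraction / mv         # mol collected
  mol * 1000 / (funnel_area_m2 * duration_h / 24)       # mmol m-2 d-1
}

#' Calibrate the chamber correction factor
#'
#' Least-squares slope of directly measured chamber fluxes on wind-model
#' fluxes. The default fit is through the origin (the correction is a pure
#' multiplicative factor); `intercept = TRUE` adds an intercept for
#' sensitivity analysis. The reported r2 is the fraction of (uncentred for
#' the origin fit) variation explained.
#'
#' @param chamber_flux,model_flux Equal-length numeric vectors, n >= 3.
#' @param intercept Fit an intercept? Default `FALSE`.
#' @return data.frame with `factor`, `r2`, `n` (and `intercept` when fitted).
#' @export
fit_correction_factor <- function(chamber_flux, model_flux, intercept = FALSE) {
  n <- length(model_flux)
  if (length(chamber_flux) != n) stop("series lengths differ", call. = FALSE)
  if (n < 3) stop("need at least 3 paired fluxes", call. = FALSE)
  if (all(model_flux == 0)) {
    stop("model fluxes are all zero: singular fit", call. = FALSE)
  }
  if (intercept) {
    fit <- stats::lm(chamber_flux ~ model_flux)
    s <- summary(fit)
    return(data.frame(factor = unname(stats::coef(fit)[2]),
                      intercept = unname(stats::coef(fit)[1]),
                      r2 = s$r.squared, n = n))
  }
  slope <- sum(chamber_flux * model_flux) / sum(model_flux^2)
  resid <- chamber_flux - slope * model_flux
  r2 <- 1 - sum(resid^2) / sum(chamber_flux^2)
  data.frame(factor = slope, r2 = r2, n = n)
}

#' Diurnal variability of a concentration or flux series
#'
#' Default is the coefficient of variation, 100 * sd/mean; `method = "range"`
#' gives 100 * (max - min)/mean instead.
#'
#' @param x Numeric series with >= 3 points and positive mean.
#' @param method `"cv"` (default) or `"range"`.
#' @return Percent variability.
#' @export
diurnal_variation <- function(x, method = c("cv", "range")) {
  method <- match.arg(method)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  m <- mean(x)
  if (!is.finite(m) || m <= 0) stop("series mean must be > 0", call. = FALSE)
  if (method == "cv") 100 * stats::sd(x) / m else 100 * (max(x) - min(x)) / m
}
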