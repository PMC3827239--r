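# Henry's law, headspace mass balance, Schmidt numbers, molar volume.

check_temperature <- function(temperature, lo = -2, hi = 40) {
  if (any(!is.finite(temperature)) ||
      any(temperature <= lo) || any(temperature >= hi)) {
    stop("temperature must lie in (", lo, ", ", hi, ") degC", call. = FALSE)
  }
  invisible(temperature)
}

#' Henry solubility adjusted to temperature
#'
#' Van 't Hoff adjustment of the reference solubility:
#' KH(T) = KH(25 degC) * exp(C * (1/T_K - 1/298.15)). Dissolution of both CO2
#' and CH4 is exothermic, so solubility decreases with temperature.
#'
#' @param species Species constants list (see [gas_species()]).
#' @param temperature Water temperature, degC; valid in (-2, 40).
#' @return Solubility, mol L-1 atm-1.
#' @examples
#' henry_constant(gas_species("CO2"), 10)
#' @export
henry_constant <- function(species, temperature) {
  check_temperature(temperature)
  t_k <- temperature + KELVIN0
  species$kh_ref * exp(species$vant_hoff * (1 / t_k - 1 / T_REF_K))
}

#' Dissolved concentration at a given partial pressure
#'
#' Henry's law: C = KH(T) * p, returned in micromolar.
#'
#' @inheritParams henry_constant
#' @param partial_pressure Gas partial pressure, atm; must be >= 0.
#' @return Concentration, uM.
#' @export
dissolved_at_partial_pressure <- function(species, temperature, partial_pressure) {
  if (any(partial_pressure < 0)) {
    stop("partial_pressure must be >= 0 atm", call. = FALSE)
  }
  henry_constant(species, temperature) * partial_pressure * 1e6
}

#' Invert a headspace equilibration to the original dissolved concentration
#'
#' A water sample (volume `water_volume_L`) is shaken to equilibrium with a
#' small headspace of ambient air (`headspace_volume_L`); the gas mixing
#' ratio measured in that headspace afterwards (`ppm_final`), together with
#' the mixing ratio of the air used (`ppm_air`), determines the original
#' dissolved concentration by mass balance:
#'
#'   C0 = KH(T) * p_eq + (p_eq - p_air) * V_h / (V_w * R * T_K)
#'
#' with p_eq = ppm_final * 1e-6 * P and p_air = ppm_air * 1e-6 * P. The first
#' term is the water-side concentration at equilibrium; the second returns
#' the gas that moved into (or out of) the headspace to the water volume.
#' `method = "henry_only"` drops the second term (pure Henry's-law readback);
#' with a 20 mL headspace over 2 L of water the difference is small.
#'
#' A negative result indicates readings inconsistent with any non-negative
#' starting concentration; it is flagged (`valid = FALSE`) and the negative
#' value is kept so QC can count and inspect such rows — never silently
#' clamped.
#'
#' @inheritParams henry_constant
#' @param water_volume_L,headspace_volume_L Volumes, L; both > 0.
#' @param ppm_final Headspace mixing ratio after equilibration, ppm.
#' @param ppm_air Mixing ratio of the ambient air used, ppm.
#' @param pressure_atm Total pressure, atm (default 1).
#' @param method `"mass_balance"` (default) or `"henry_only"`.
#' @return data.frame with columns `conc_uM` and `valid` (one row per input).
#' @examples
#' sp <- gas_species("CH4")
#' headspace_to_dissolved(sp, water_volume_L = 2, headspace_volume_L = 0.02,
#'                        temperature = 10, ppm_final = 250, ppm_air = 1.8)
#' @export
headspace_to_dissolved <- function(species, water_volume_L, headspace_volume_L,
                                   temperature, ppm_final, ppm_air,
                                   pressure_atm = 1,
                                   method = c("mass_balance", "henry_only")) {
  method <- match.arg(method)
  if (any(water_volume_L <= 0) || any(headspace_volume_L <= 0)) {
    stop("water and headspace volumes must be > 0 L", call. = FALSE)
  }
  if (any(ppm_final < 0)) stop("ppm_final must be >= 0", call. = FALSE)
  if (any(pressure_atm <= 0) || any(pressure_atm > 1.2)) {
    stop("pressure_atm must lie in (0, 1.2] atm", call. = FALSE)
  }
  check_temperature(temperature)
  t_k <- temperature + KELVIN0
  p_eq <- ppm_final * 1e-6 * pressure_atm
  p_air <- ppm_air * 1e-6 * pressure_atm
  kh <- henry_constant(species, temperature)
  conc_molL <- kh * p_eq
  if (method == "mass_balance") {
    conc_molL <- conc_molL +
      (p_eq - p_air) * headspace_volume_L / (water_volume_L * R_GAS * t_k)
  }
  conc <- conc_molL * 1e6
  data.frame(conc_uM = conc, valid = conc >= 0)
}

#' Schmidt number from the freshwater temperature polynomial
#'
#' Third-order polynomial in water temperature (degC) with the configured
#' freshwater coefficients. With the defaults, Sc(CO2, 20 degC) is about 600,
#' the reference point of the k600 normalisation.
#'
#' @inheritParams henry_constant
#' @param temperature Water temperature, degC; valid in [0, 30].
#' @return Dimensionless Schmidt number.
#' @export
schmidt_number <- function(species, temperature) {
  if (any(!is.finite(temperature)) ||
      any(temperature < 0) || any(temperature > 30)) {
    stop("temperature must lie in [0, 30] degC for the Schmidt polynomial",
         call. = FALSE)
  }
  cf <- species$schmidt_coeffs
  cf[1] + cf[2] * temperature + cf[3] * temperature^2 + cf[4] * temperature^3
}

#' Ideal-gas molar volume
#'
#' MV = R * T_K / P. At 0 degC and 1 atm this is 22.414 L mol-1.
#'
#' @param temperature Air temperature, degC.
#' @param pressure_atm Pressure, atm; must be > 0.
#' @return Molar volume, L mol-1.
#' @export
molar_volume <- function(temperature, pressure_atm = 1) {
  if (any(pressure_atm <= 0)) stop("pressure_atm must be > 0", call. = FALSE)
  R_GAS * (temperature + KELVIN0) / pressure_atm
}

#' Read a headspace-equilibration table
#'
#' Required columns: `pond_id`, `species`, `water_volume_L`,
#' `headspace_volume_mL`, `temp_C`, `ppm_final`, `ppm_air`. An optional
#' `pressure_atm` column defaults to 1.
#'
#' @param path CSV path.
#' @return data.frame with the validated columns (`headspace_volume_mL` kept
#'   in mL as read).
#' @export
read_headspace_csv <- function(path) {
  read_table_csv(path, c("pond_id", "species", "water_volume_L",
                         "headspace_volume_mL", "temp_C", "ppm_final",
                         "ppm_air"))
}

#' Compute dissolved concentrations for a whole headspace table
#'
#' Applies [headspace_to_dissolved()] row-wise to a table in the
#' [read_headspace_csv()] schema.
#'
#' @param headspace data.frame in the headspace schema.
#' @param constants Constants bundle from [gas_constants()].
#' @param method Passed to [headspace_to_dissolved()].
#' @return The input with `conc_uM` and `valid` columns appended.
#' @export
dissolved_from_headspace <- function(headspace, constants = gas_constants(),
                                     method = "mass_balance") {
  pressure <- if ("pressure_atm" %in% names(headspace)) {
    headspace$pressure_atm
  } else {
    rep(1, nrow(headspace))
  }
  out <- headspace
  out$conc_uM <- NA_real_
  out$valid <- NA
  for (sp in unique(headspace$species)) {
    i <- headspace$species == sp
    res <- headspace_to_dissolved(
      gas_species(sp, constants),
      water_volume_L = headspace$water_volume_L[i],
      headspace_volume_L = headspace$headspace_volume_mL[i] / 1000,
      temperature = headspace$temp_C[i],
      ppm_final = headspace$ppm_final[i],
      ppm_air = headspace$ppm_air[i],
      pressure_atm = pressure[i],
      method = method
    )
    out$conc_uM[i] <- res$conc_uM
    out$valid[i] <- res$valid
  }
  out
}
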