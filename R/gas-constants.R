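#' @keywords internal
"_PACKAGE"

# Ideal gas constant, L atm mol-1 K-1
R_GAS <- 0.082057338

KELVIN0 <- 273.15
T_REF_K <- 298.15

#' Physical constants for the supported gas species
#'
#' Returns the constants bundle used throughout the package: Henry solubility
#' at 25 degC with its van 't Hoff temperature coefficient, the freshwater
#' Schmidt-number polynomial coefficients (third order in temperature, degC),
#' and the default atmospheric dry-air mixing ratio.
#'
#' Defaults are the standard freshwater values: CO2 solubility
#' 3.4e-2 mol L-1 atm-1 (2400 K), CH4 1.4e-3 mol L-1 atm-1 (1700 K), and the
#' Wanninkhof freshwater Schmidt polynomials, which give Sc(CO2, 20 degC)
#' close to 600 — the normalisation point of the k600 convention. Atmospheric
#' mixing ratios default to 390 ppm CO2 and 1.8 ppm CH4. Every value can be
#' overridden, so site-specific constants never require code changes.
#'
#' @param overrides Named list of per-species overrides, e.g.
#'   `list(CO2 = list(atm_mixing_ratio = 395))`.
#' @return Named list with one element per species (`CO2`, `CH4`), each a
#'   list with `name`, `kh_ref` (mol L-1 atm-1), `vant_hoff` (K),
#'   `schmidt_coeffs` (length-4 numeric, a0..a3) and `atm_mixing_ratio` (ppm).
#' @examples
#' gas_constants()$CH4$kh_ref
#' gas_constants(list(CO2 = list(atm_mixing_ratio = 400)))$CO2$atm_mixing_ratio
#' @export
gas_constants <- function(overrides = NULL) {
  defaults <- list(
    CO2 = list(
      name = "CO2",
      kh_ref = 3.4e-2,
      vant_hoff = 2400,
      schmidt_coeffs = c(1911.1, -118.11, 3.4527, -0.041320),
      atm_mixing_ratio = 390
    ),
    CH4 = list(
      name = "CH4",
      kh_ref = 1.4e-3,
      vant_hoff = 1700,
      schmidt_coeffs = c(1897.8, -114.28, 3.2902, -0.039061),
      atm_mixing_ratio = 1.8
    )
  )
  if (!is.null(overrides)) {
    for (sp in names(overrides)) {
      if (!sp %in% names(defaults)) {
        stop("unknown species in overrides: ", sp, call. = FALSE)
      }
      for (field in names(overrides[[sp]])) {
        if (!field %in% names(defaults[[sp]])) {
          stop("unknown constant field: ", sp, "$", field, call. = FALSE)
        }
        defaults[[sp]][[field]] <- overrides[[sp]][[field]]
      }
    }
  }
  for (sp in names(defaults)) validate_gas_species(defaults[[sp]])
  defaults
}

#' Look up one gas species' constants
#'
#' @param name `"CO2"` or `"CH4"`.
#' @param constants Constants bundle from [gas_constants()].
#' @return A single species constants list.
#' @export
gas_species <- function(name, constants = gas_constants()) {
  name <- toupper(as.character(name))
  if (length(name) != 1L || !name %in% names(constants)) {
    stop("unknown gas species: ", paste(name, collapse = ","),
         " (supported: ", paste(names(constants), collapse = ", "), ")",
         call. = FALSE)
  }
  constants[[name]]
}

validate_gas_species <- function(sp) {
  stopifnot(
    sp$kh_ref > 0,
    sp$vant_hoff > 0,
    length(sp$schmidt_coeffs) == 4L,
    sp$atm_mixing_ratio > 0
  )
  tt <- seq(0, 30, by = 1)
  sc <- sp$schmidt_coeffs[1] + sp$schmidt_coeffs[2] * tt +
    sp$schmidt_coeffs[3] * tt^2 + sp$schmidt_coeffs[4] * tt^3
  if (any(sc <= 0)) {
    stop("Schmidt polynomial for ", sp$name,
         " is not positive over 0-30 degC", call. = FALSE)
  }
  invisible(sp)
}

#' Read or write a plain-text gas-constants file
#'
#' The file format is `species.field = value` per line, `#` comments allowed;
#' `schmidt_coeffs` is four comma-separated numbers. Fields not present in the
#' file keep their defaults.
#'
#' @param path File path.
#' @param constants Constants bundle to write.
#' @return `read_gas_constants()` returns a constants bundle;
#'   `write_gas_constants()` returns `path` invisibly.
#' @export
read_gas_constants <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed constants line: ", ln, call. = FALSE)
    key <- strsplit(trimws(kv[1]), ".", fixed = TRUE)[[1]]
    if (length(key) != 2L) stop("expected species.field key in: ", ln, call. = FALSE)
    val <- trimws(kv[2])
    val <- if (key[2] == "name") val else
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    overrides[[key[1]]][[key[2]]] <- val
  }
  gas_constants(overrides)
}

#' @rdname read_gas_constants
#' @export
write_gas_constants <- function(constants, path) {
  lines <- character(0)
  for (sp in names(constants)) {
    s <- constants[[sp]]
    lines <- c(
      lines,
      sprintf("%s.kh_ref = %.10g", sp, s$kh_ref),
      sprintf("%s.vant_hoff = %.10g", sp, s$vant_hoff),
      sprintf("%s.schmidt_coeffs = %s", sp,
              paste(format(s$schmidt_coeffs, digits = 10), collapse = ", ")),
      sprintf("%s.atm_mixing_ratio = %.10g", sp, s$atm_mixing_ratio)
    )
  }
  writeLines(lines, path)
  invisible(path)
}
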