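# Shared CSV schema helpers. All tabular I/O is plain CSV with named columns;
# schema violations are reported with the file and the missing columns.

read_table_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a wind record table
#'
#' Required columns: `timestamp` (parseable as `YYYY-MM-DD HH:MM:SS`, UTC)
#' and `u10_ms` (wind speed at 10 m, m s-1).
#'
#' @param path CSV path.
#' @return data.frame with `timestamp` as POSIXct (UTC) and `u10_ms`.
#' @export
read_wind_csv <- function(path) {
  df <- read_table_csv(path, c("timestamp", "u10_ms"))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  if (any(df$u10_ms < 0)) stop("u10_ms must be >= 0 in ", path, call. = FALSE)
  df
}

#' Read a funnel-collection table
#'
#' Required columns: `pond_id`, `start`, `end` (timestamps), `volume_mL`,
#' `ch4_frac` (volume fraction in [0, 1]), `air_temp_C`. Optional
#' `pressure_atm`, `funnel_area_m2`.
#'
#' @param path CSV path.
#' @return data.frame with parsed timestamps.
#' @export
read_funnel_csv <- function(path) {
  df <- read_table_csv(path, c("pond_id", "start", "end", "volume_mL",
                               "ch4_frac", "air_temp_C"))
  df$start <- as.POSIXct(df$start, tz = "UTC")
  df$end <- as.POSIXct(df$end, tz = "UTC")
  df
}

#' Read a stable-isotope sample table
#'
#' Required columns: `pond_id`, `transport` (`diffusion`|`ebullition`),
#' `d13c_ch4`. Optional: `dd_ch4`, `d13c_co2`, `o2_mgL`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_isotope_csv <- function(path) {
  read_table_csv(path, c("pond_id", "transport", "d13c_ch4"))
}

#' Read a radiocarbon sample table
#'
#' Required columns: `pond_id`, `species`, `transport`, `delta14c_permil`,
#' `year`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_radiocarbon_csv <- function(path) {
  read_table_csv(path, c("pond_id", "species", "transport",
                         "delta14c_permil", "year"))
}
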