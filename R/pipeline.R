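# Orchestration: group contrasts, landscape upscaling, and the full report
# pipeline (dissolved -> fluxes -> ebullition -> isotopes -> radiocarbon ->
# comparisons -> upscaling). The t statistics are computed from their
# defining formulas so each stage can be verified against an independent
# oracle.

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value from the t distribution, computed from the
#' formulas:
#' t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b).
#'
#' @param group_a,group_b Numeric vectors, each n >= 2 with finite variance.
#' @return data.frame with `statistic`, `df`, `p`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`.
#' @export
welch_t_test <- function(group_a, group_b) {
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2", call. = FALSE)
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (!is.finite(va) || !is.finite(vb)) {
    stop("non-finite group variance", call. = FALSE)
  }
  se2 <- va / n_a + vb / n_b
  if (se2 == 0) {
    # identical constant groups: no evidence of a difference
    return(data.frame(statistic = 0, df = n_a + n_b - 2, p = 1,
                      mean_a = mean(group_a), mean_b = mean(group_b),
                      n_a = n_a, n_b = n_b))
  }
  t_stat <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((va / n_a)^2 / (n_a - 1) + (vb / n_b)^2 / (n_b - 1))
  data.frame(statistic = t_stat, df = df,
             p = 2 * stats::pt(-abs(t_stat), df),
             mean_a = mean(group_a), mean_b = mean(group_b),
             n_a = n_a, n_b = n_b)
}

#' Paired (one-sample) t test on differences
#'
#' t = mean(d) / (sd(d)/sqrt(n)), df = n - 1, two-sided p. Zero-spread
#' differences are degenerate: all-zero differences give t = 0, p = 1;
#' constant nonzero differences are flagged (`degenerate = TRUE`) with
#' p = 0 reported as the formal limit.
#'
#' @param differences Numeric vector of paired differences, n >= 2.
#' @return data.frame with `statistic`, `df`, `p`, `mean_diff`, `n`,
#'   `degenerate`.
#' @export
paired_t_test <- function(differences) {
  n <- length(differences)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  m <- mean(differences)
  s <- stats::sd(differences)
  if (s == 0) {
    if (m == 0) {
      return(data.frame(statistic = 0, df = n - 1, p = 1, mean_diff = 0,
                        n = n, degenerate = FALSE))
    }
    return(data.frame(statistic = sign(m) * Inf, df = n - 1, p = 0,
                      mean_diff = m, n = n, degenerate = TRUE))
  }
  t_stat <- m / (s / sqrt(n))
  data.frame(statistic = t_stat, df = n - 1,
             p = 2 * stats::pt(-abs(t_stat), n - 1),
             mean_diff = m, n = n, degenerate = FALSE)
}

#' Landscape emission shares from areas and areal fluxes
#'
#' share_i = area_i * flux_i / sum_j(area_j * flux_j). Area fractions need
#' not sum to 1 (other surface types may be excluded); shares always do.
#' With equal fluxes the shares reduce to the renormalised area fractions:
#' areas of 44% and 27% give 44/71 and 27/71.
#'
#' @param area_fractions Named nonnegative vector of per-type area fractions.
#' @param mean_fluxes Named nonnegative vector of per-type mean areal fluxes
#'   (same names).
#' @return data.frame with `type`, `area_fraction`, `mean_flux`, `share`;
#'   shares sum to 1.
#' @export
landscape_upscale <- function(area_fractions, mean_fluxes) {
  if (is.null(names(area_fractions)) || is.null(names(mean_fluxes))) {
    stop("area_fractions and mean_fluxes must be named", call. = FALSE)
  }
  types <- names(area_fractions)
  if (!setequal(types, names(mean_fluxes))) {
    stop("type names differ between areas and fluxes", call. = FALSE)
  }
  mean_fluxes <- mean_fluxes[types]
  if (any(area_fractions < 0) || any(mean_fluxes < 0)) {
    stop("areas and fluxes must be >= 0", call. = FALSE)
  }
  prod <- area_fractions * mean_fluxes
  if (sum(prod) == 0) {
    stop("all area x flux products are zero: shares undefined", call. = FALSE)
  }
  data.frame(type = types,
             area_fraction = unname(area_fractions),
             mean_flux = unname(mean_fluxes),
             share = unname(prod / sum(prod)))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(stage, " stage: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline on a campaign
#'
#' Executes dissolved concentrations (headspace inversion), diffusive fluxes
#' (2 h wind window, Schmidt scaling, chamber correction), ebullition
#' fluxes, isotope pathway classification, radiocarbon apportionment,
#' runnel-vs-polygonal Welch contrasts, and CH4 landscape upscaling. The
#' report is a pure function of the inputs and configuration: re-running
#' yields identical tables. Stage failures are reported with the stage name;
#' when writing to `out`, tables from completed stages are left intact.
#'
#' @param campaign A `pond_campaign` from [generate_campaign()], or a
#'   directory written by [write_campaign()].
#' @param out Optional directory; each stage table is written as CSV there,
#'   plus a `report_manifest.txt`.
#' @param constants Gas constants bundle.
#' @param correction Chamber correction factor applied to diffusive fluxes.
#' @param wind_window_h Wind averaging window, hours.
#' @param boundaries,windows Isotope classification configuration.
#' @param endmembers Radiocarbon endmembers.
#' @param area_fractions Named per-type open-water area fractions for
#'   upscaling.
#' @param headspace_method Passed to [dissolved_from_headspace()].
#' @return list of class `pond_report` with `dissolved`, `fluxes`,
#'   `ebullition`, `isotopes`, `radiocarbon`, `comparisons`, `landscape`,
#'   `n_tests`.
#' @export
run_report <- function(campaign, out = NULL,
                       constants = gas_constants(),
                       correction = 0.2458,
                       wind_window_h = 2,
                       boundaries = cd_boundaries(),
                       windows = alpha_windows(),
                       endmembers = endmember_pair(),
                       area_fractions = c(runnel = 0.44, polygonal = 0.27),
                       headspace_method = "mass_balance") {
  if (is.character(campaign)) campaign <- read_campaign(campaign)
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out)) {
      utils::write.csv(df, file.path(out, paste0(name, ".csv")),
                       row.names = FALSE)
    }
    df
  }
  report <- list()

  # dissolved concentrations
  report$dissolved <- with_stage("dissolved", {
    hs <- campaign$headspace
    if (is.null(hs)) stop("headspace table missing")
    d <- dissolved_from_headspace(hs, constants, method = headspace_method)
    emit(d[c("pond_id", "species", "timestamp", "temp_C", "conc_uM", "valid")],
         "dissolved")
  })

  # diffusive fluxes
  report$fluxes <- with_stage("flux", {
    wind <- campaign$wind
    if (is.null(wind)) stop("wind table missing")
    d <- report$dissolved
    at <- as.POSIXct(d$timestamp, tz = "UTC")
    u10m <- vapply(seq_len(nrow(d)), function(i) {
      wind_window_mean(wind, at[i], wind_window_h)
    }, numeric(1))
    rows <- lapply(unique(d$species), function(sp_name) {
      sp <- gas_species(sp_name, constants)
      i <- d$species == sp_name
      k600 <- k600_cole(u10m[i])
      sc <- schmidt_number(sp, d$temp_C[i])
      k <- transfer_velocity(k600, sc, u10m[i])
      c_eq <- equilibrium_concentration(sp, d$temp_C[i])
      fx <- diffusive_flux(sp, d$conc_uM[i], c_eq, k, correction,
                           k600 = k600, schmidt = sc)
      cbind(data.frame(pond_id = d$pond_id[i], timestamp = d$timestamp[i],
                       u10_mean = u10m[i]), fx)
    })
    emit(do.call(rbind, rows), "fluxes")
  })

  # ebullition
  report$ebullition <- with_stage("ebullition", {
    fn <- campaign$funnels
    if (is.null(fn) || nrow(fn) == 0) {
      data.frame()
    } else {
      dur_h <- if ("duration_h" %in% names(fn)) fn$duration_h else {
        as.numeric(difftime(as.POSIXct(fn$end, tz = "UTC"),
                            as.POSIXct(fn$start, tz = "UTC"), units = "hours"))
      }
      area <- if ("funnel_area_m2" %in% names(fn)) fn$funnel_area_m2 else 0.3526
      press <- if ("pressure_atm" %in% names(fn)) fn$pressure_atm else 1
      fn$duration_h <- dur_h
      fn$flux_mmol_m2_d <- ebullition_flux(fn$volume_mL, dur_h, fn$ch4_frac,
                                           fn$air_temp_C, area, press)
      emit(fn, "ebullition")
    }
  })

  # isotopes
  report$isotopes <- with_stage("isotopes", {
    iso <- campaign$isotopes
    if (is.null(iso) || nrow(iso) == 0) data.frame()
    else emit(classify_isotopes(iso, boundaries, windows), "isotopes")
  })

  # radiocarbon
  report$radiocarbon <- with_stage("radiocarbon", {
    c14 <- campaign$radiocarbon
    if (is.null(c14) || nrow(c14) == 0) data.frame()
    else emit(radiocarbon_table(c14, endmembers), "radiocarbon")
  })

  # runnel vs polygonal contrasts (concentration and diffusive flux)
  report$comparisons <- with_stage("comparisons", {
    ponds <- campaign$ponds
    if (is.null(ponds)) stop("pond table missing")
    type_of <- stats::setNames(ponds$type, ponds$pond_id)
    rows <- list()
    for (sp_name in unique(report$dissolved$species)) {
      for (qty in c("conc_uM", "flux_mmol_m2_d")) {
        tab <- if (qty == "conc_uM") report$dissolved else report$fluxes
        tab <- tab[tab$species == sp_name, ]
        ty <- type_of[tab$pond_id]
        w <- welch_t_test(tab[[qty]][ty == "runnel"],
                          tab[[qty]][ty == "polygonal"])
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(species = sp_name, quantity = qty), w)
      }
    }
    cmp <- do.call(rbind, rows)
    names(cmp)[names(cmp) == "mean_a"] <- "mean_runnel"
    names(cmp)[names(cmp) == "mean_b"] <- "mean_polygonal"
    names(cmp)[names(cmp) == "n_a"] <- "n_runnel"
    names(cmp)[names(cmp) == "n_b"] <- "n_polygonal"
    emit(cmp, "comparisons")
  })
  report$n_tests <- nrow(report$comparisons)

  # CH4 landscape upscaling (diffusive means per type)
  report$landscape <- with_stage("upscaling", {
    fx <- report$fluxes[report$fluxes$species == "CH4", ]
    ty <- stats::setNames(campaign$ponds$type, campaign$ponds$pond_id)[fx$pond_id]
    mean_flux <- vapply(names(area_fractions), function(t) {
      mean(fx$flux_mmol_m2_d[ty == t])
    }, numeric(1))
    emit(landscape_upscale(area_fractions, pmax(mean_flux, 0)), "landscape")
  })

  if (!is.null(out)) {
    writeLines(c(
      paste0("pondgas ", as.character(utils::packageVersion("pondgas"))),
      paste0("correction: ", correction),
      paste0("wind_window_h: ", wind_window_h),
      paste0("welch_tests_performed: ", report$n_tests),
      "multiple_testing_correction: none"
    ), file.path(out, "report_manifest.txt"))
  }
  class(report) <- "pond_report"
  report
}

#' @export
print.pond_report <- function(x, ...) {
  cat("Thaw-pond GHG report\n")
  cat("  dissolved samples:", nrow(x$dissolved),
      "| flux estimates:", nrow(x$fluxes),
      "| funnel collections:", nrow(x$ebullition), "\n")
  if (nrow(x$comparisons)) {
    cat("  runnel vs polygonal contrasts (Welch, two-sided, uncorrected):\n")
    for (i in seq_len(nrow(x$comparisons))) {
      r <- x$comparisons[i, ]
      cat(sprintf("    %s %-14s t = %6.2f, df = %5.1f, p = %.4g\n",
                  r$species, r$quantity, r$statistic, r$df, r$p))
    }
  }
  if (nrow(x$landscape)) {
    cat("  CH4 emission shares:\n")
    for (i in seq_len(nrow(x$landscape))) {
      cat(sprintf("    %-10s area %4.0f%%  share %5.1f%%\n",
                  x$landscape$type[i], 100 * x$landscape$area_fraction[i],
                  100 * x$landscape$share[i]))
    }
  }
  invisible(x)
}
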