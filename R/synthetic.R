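# Seeded synthetic field-campaign generator. Emulates the sampling design of
# a short Arctic summer campaign on two thaw-pond types (polygonal, runnel):
# per-pond dissolved CO2/CH4 drawn from right-skewed group distributions,
# headspace GC readings forward-simulated from the equilibration mass
# balance, an hourly wind record, funnel ebullition collections, pathway-
# consistent stable-isotope samples and endmember-mixed radiocarbon samples.
# Every observational row is traceable to a ground-truth row, so parameter
# recovery can be tested at each pipeline stage.

#' Lognormal parameters matching a target mean and sd
#'
#' Moment matching: mu = ln(mean^2 / sqrt(mean^2 + sd^2)),
#' sigma^2 = ln(1 + sd^2/mean^2). `sd = 0` degenerates to a point mass
#' (sigma = 0).
#'
#' @param mean,sd Target arithmetic mean (> 0) and sd (>= 0).
#' @return list with `meanlog`, `sdlog`.
#' @export
lognormal_from_mean_sd <- function(mean, sd) {
  if (any(mean <= 0)) stop("mean must be > 0", call. = FALSE)
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  cv2 <- (sd / mean)^2
  list(meanlog = log(mean^2 / sqrt(mean^2 + sd^2)), sdlog = sqrt(log(1 + cv2)))
}

#' Configuration of a synthetic thaw-pond campaign
#'
#' Defaults reproduce the structure of the emulated field study: 33
#' polygonal and 58 runnel ponds; dissolved CO2 119 +/- 124 uM (runnel) vs
#' 9.6 +/- 8.9 uM (polygonal) and CH4 4.1 +/- 4.7 vs 1.3 +/- 1.7 uM, drawn
#' from moment-matched lognormals; an hourly wind record with mean 4 m s-1
#' and 45% coefficient of variation; 2 L water / 20 mL headspace
#' equilibrations with 2% multiplicative GC noise; funnel collections on two
#' polygonal ponds (8 each, 12-32 h) with bubble CH4 fractions in
#' [1.5%, 32%] and fluxes capped at 2.13 mmol m-2 d-1; acetoclastic-pathway
#' isotope samples with instrument noise (+/- 0.2 permil C, +/- 3 permil D);
#' radiocarbon samples mixed from a post-bomb modern endmember and a
#' basal-peat old endmember, with a higher old-carbon fraction in runnel
#' ponds, and 2.8 permil measurement noise.
#'
#' @param n_polygonal,n_runnel Pond counts per type.
#' @param seed Integer seed; the campaign is a pure function of the config.
#' @param ... Overrides of any default listed below.
#' @return list of class `campaign_config`.
#' @export
campaign_config <- function(n_polygonal = 33, n_runnel = 58, seed = 1, ...) {
  cfg <- list(
    n_polygonal = n_polygonal,
    n_runnel = n_runnel,
    seed = seed,
    start = "2011-06-20 00:00:00",
    days = 21,
    # dissolved concentration mean/sd per species and pond type, uM
    conc = list(
      CO2 = list(runnel = c(mean = 119, sd = 124),
                 polygonal = c(mean = 9.6, sd = 8.9)),
      CH4 = list(runnel = c(mean = 4.1, sd = 4.7),
                 polygonal = c(mean = 1.3, sd = 1.7))
    ),
    wind_mean_ms = 4,
    wind_cv = 0.45,
    water_temp_range = c(4, 16),
    air_temp_range = c(2, 18),
    pressure_atm = 1,
    water_volume_L = 2,
    headspace_volume_mL = 20,
    gc_noise_cv = 0.02,
    correction = 0.2458,
    wind_window_h = 2,
    # ebullition design (funnels installable on polygonal ponds only)
    n_funnel_ponds = 2,
    n_collections = 8,
    funnel_area_m2 = 0.3526,
    duration_range_h = c(12, 32),
    bubble_ch4_range = c(0.015, 0.32),
    ebullition_cap = 2.13,
    ebullition_mean_sd = c(mean = 0.6, sd = 0.6),
    # stable isotopes
    n_iso_diffusion = c(polygonal = 9, runnel = 10),
    n_iso_ebullition = c(polygonal = 2, runnel = 2),
    pathway_mix = c(acetoclastic = 1, hydrogenotrophic = 0),
    d13c_noise = 0.2,
    dd_noise = 3,
    o2_range = list(polygonal = c(6, 12), runnel = c(2, 8)),
    oxidation_slope = 0,
    # radiocarbon
    n_c14 = c(polygonal = 7, runnel = 3),
    f_old_range = list(polygonal = c(0, 0.03), runnel = c(0.03, 0.12)),
    c14_year = 2011,
    c14_noise_permil = 2.8,
    endmembers = endmember_pair(),
    # landscape areas (fraction of valley open water per type)
    area_fractions = c(runnel = 0.44, polygonal = 0.27)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm, call. = FALSE)
    cfg[[nm]] <- dots[[nm]]
  }
  validate_campaign_config(cfg)
  class(cfg) <- "campaign_config"
  cfg
}

validate_campaign_config <- function(cfg) {
  if (cfg$n_polygonal < 1 || cfg$n_runnel < 1) {
    stop("pond counts must be >= 1", call. = FALSE)
  }
  for (sp in names(cfg$conc)) for (ty in names(cfg$conc[[sp]])) {
    v <- cfg$conc[[sp]][[ty]]
    if (v[["mean"]] <= 0 || v[["sd"]] < 0) {
      stop("concentration mean must be > 0 and sd >= 0 for ",
           sp, "/", ty, call. = FALSE)
    }
  }
  if (cfg$wind_cv < 0 || cfg$gc_noise_cv < 0 || cfg$d13c_noise < 0 ||
      cfg$dd_noise < 0 || cfg$c14_noise_permil < 0) {
    stop("noise levels must be >= 0", call. = FALSE)
  }
  rng <- cfg$bubble_ch4_range
  if (rng[1] < 0 || rng[2] > 1 || rng[1] > rng[2]) {
    stop("bubble_ch4_range must be an interval within [0, 1]", call. = FALSE)
  }
  for (ty in names(cfg$f_old_range)) {
    fr <- cfg$f_old_range[[ty]]
    if (fr[1] < 0 || fr[2] > 1 || fr[1] > fr[2]) {
      stop("f_old_range must be an interval within [0, 1]", call. = FALSE)
    }
  }
  n_of <- c(polygonal = cfg$n_polygonal, runnel = cfg$n_runnel)
  for (cnt in list(cfg$n_iso_diffusion, cfg$n_iso_ebullition)) {
    for (ty in names(cnt)) {
      if (cnt[[ty]] > n_of[[ty]]) {
        stop("isotope sample count exceeds the number of ", ty, " ponds",
             call. = FALSE)
      }
    }
  }
  if (cfg$n_funnel_ponds > cfg$n_polygonal) {
    stop("n_funnel_ponds exceeds the number of polygonal ponds", call. = FALSE)
  }
  invisible(cfg)
}

# Forward headspace partitioning: equilibrium mixing ratio (ppm) reached in
# the headspace when water at true concentration c0_uM is equilibrated with
# air at ppm_air. Closed-form solution of the same mass balance that
# headspace_to_dissolved() inverts.
forward_headspace_ppm <- function(species, c0_uM, water_volume_L,
                                  headspace_volume_L, temperature,
                                  ppm_air, pressure_atm = 1) {
  t_k <- temperature + KELVIN0
  kh <- henry_constant(species, temperature)
  b <- headspace_volume_L / (R_GAS * t_k)          # mol atm-1 in headspace
  p_air <- ppm_air * 1e-6 * pressure_atm
  total <- c0_uM * 1e-6 * water_volume_L + p_air * b
  p_eq <- total / (kh * water_volume_L + b)
  p_eq / pressure_atm * 1e6
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Generate a synthetic field campaign
#'
#' Draws a complete campaign (pond, wind, headspace, funnel, isotope and
#' radiocarbon tables) plus ground truth, reproducibly from `config$seed`.
#' Identical configs give byte-identical campaigns. With all noise levels
#' set to zero the full analysis pipeline recovers the ground truth exactly.
#'
#' @param config From [campaign_config()].
#' @param constants Gas constants bundle.
#' @return list of class `pond_campaign` with elements `config`, `ponds`,
#'   `wind`, `headspace`, `funnels`, `isotopes`, `radiocarbon` and `truth`
#'   (a list of per-stage ground-truth data frames).
#' @export
generate_campaign <- function(config = campaign_config(),
                              constants = gas_constants()) {
  validate_campaign_config(config)
  set.seed(config$seed)
  start <- as.POSIXct(config$start, tz = "UTC")

  # --- ponds ---------------------------------------------------------------
  n_p <- config$n_polygonal
  n_r <- config$n_runnel
  ponds <- data.frame(
    pond_id = c(sprintf("P%02d", seq_len(n_p)), sprintf("R%02d", seq_len(n_r))),
    type = c(rep("polygonal", n_p), rep("runnel", n_r)),
    area_m2 = c(runif_range(n_p, c(50, 500)), runif_range(n_r, c(20, 200))),
    depth_m = c(runif_range(n_p, c(0.5, 1.5)), runif_range(n_r, c(0.2, 0.5)))
  )

  # --- wind record (hourly, iid lognormal with configured CV) --------------
  n_hours <- config$days * 24
  wpar <- lognormal_from_mean_sd(config$wind_mean_ms,
                                 config$wind_mean_ms * config$wind_cv)
  wind <- data.frame(
    timestamp = start + (seq_len(n_hours) - 1) * 3600,
    u10_ms = stats::rlnorm(n_hours, wpar$meanlog, wpar$sdlog)
  )

  # --- true dissolved concentrations and headspace readings ----------------
  species <- names(config$conc)
  n_ponds <- nrow(ponds)
  hs <- truth_diss <- truth_flux <- vector("list", length(species))
  for (j in seq_along(species)) {
    sp_name <- species[j]
    sp <- gas_species(sp_name, constants)
    par_by_type <- config$conc[[sp_name]]
    conc <- numeric(n_ponds)
    for (ty in names(par_by_type)) {
      i <- ponds$type == ty
      lp <- lognormal_from_mean_sd(par_by_type[[ty]][["mean"]],
                                   par_by_type[[ty]][["sd"]])
      conc[i] <- stats::rlnorm(sum(i), lp$meanlog, lp$sdlog)
    }
    # one discrete sample per pond, daytime (09:00-16:00), random day
    day <- sample.int(config$days, n_ponds, replace = TRUE) - 1
    hour <- runif_range(n_ponds, c(9, 16))
    at <- start + day * 86400 + round(hour * 3600)
    temp <- runif_range(n_ponds, config$water_temp_range)
    ppm_air <- rep(sp$atm_mixing_ratio, n_ponds)
    ppm_true <- forward_headspace_ppm(
      sp, conc, config$water_volume_L, config$headspace_volume_mL / 1000,
      temp, ppm_air, config$pressure_atm
    )
    hs[[j]] <- data.frame(
      pond_id = ponds$pond_id,
      species = sp_name,
      timestamp = format(at, "%Y-%m-%d %H:%M:%S"),
      water_volume_L = config$water_volume_L,
      headspace_volume_mL = config$headspace_volume_mL,
      temp_C = temp,
      pressure_atm = config$pressure_atm,
      ppm_final = ppm_true * mult_noise(n_ponds, config$gc_noise_cv),
      ppm_air = ppm_air
    )
    truth_diss[[j]] <- data.frame(pond_id = ponds$pond_id, species = sp_name,
                                  conc_uM = conc)
    # true diffusive flux implied by the generative model
    u10m <- vapply(seq_len(n_ponds), function(i) {
      wind_window_mean(wind, at[i], config$wind_window_h)
    }, numeric(1))
    k600 <- k600_cole(u10m)
    sc <- schmidt_number(sp, temp)
    k <- transfer_velocity(k600, sc, u10m)
    c_eq <- equilibrium_concentration(sp, temp, config$pressure_atm)
    truth_flux[[j]] <- data.frame(
      pond_id = ponds$pond_id, species = sp_name,
      u10_mean = u10m, k600_cm_h = k600, schmidt = sc, k_m_d = k,
      c_equilibrium_uM = c_eq,
      flux_mmol_m2_d = config$correction * k * (conc - c_eq)
    )
  }
  headspace <- do.call(rbind, hs)

  # --- funnel collections (polygonal ponds only, as installable) -----------
  fp <- ponds$pond_id[ponds$type == "polygonal"][seq_len(config$n_funnel_ponds)]
  n_coll <- config$n_collections * length(fp)
  epar <- lognormal_from_mean_sd(config$ebullition_mean_sd[["mean"]],
                                 config$ebullition_mean_sd[["sd"]])
  true_eflux <- stats::rlnorm(n_coll, epar$meanlog, epar$sdlog)
  while (any(true_eflux > config$ebullition_cap)) {     # truncation at the cap
    i <- true_eflux > config$ebullition_cap
    true_eflux[i] <- stats::rlnorm(sum(i), epar$meanlog, epar$sdlog)
  }
  dur_h <- runif_range(n_coll, config$duration_range_h)
  frac <- runif_range(n_coll, config$bubble_ch4_range)
  air_t <- runif_range(n_coll, config$air_temp_range)
  f_start <- start + (sample.int(config$days, n_coll, replace = TRUE) - 1) *
    86400 + round(runif_range(n_coll, c(8, 12)) * 3600)
  mv <- molar_volume(air_t, config$pressure_atm)
  vol_mL <- true_eflux / 1000 * config$funnel_area_m2 * (dur_h / 24) *
    mv / frac * 1000
  funnels <- data.frame(
    pond_id = rep(fp, each = config$n_collections),
    start = format(f_start, "%Y-%m-%d %H:%M:%S"),
    end = format(f_start + round(dur_h * 3600), "%Y-%m-%d %H:%M:%S"),
    volume_mL = vol_mL,
    ch4_frac = frac,
    air_temp_C = air_t,
    pressure_atm = config$pressure_atm,
    funnel_area_m2 = config$funnel_area_m2,
    duration_h = dur_h
  )
  truth_ebul <- data.frame(pond_id = funnels$pond_id, start = funnels$start,
                           flux_mmol_m2_d = true_eflux)

  # --- stable isotopes -----------------------------------------------------
  iso_rows <- list()
  draw_iso <- function(pond_ids, types, transport) {
    n <- length(pond_ids)
    mix <- config$pathway_mix / sum(config$pathway_mix)
    pathway <- sample(names(mix), n, replace = TRUE, prob = mix)
    d13c <- dd <- alpha <- numeric(n)
    am <- pathway == "acetoclastic"
    # interior draws: margins keep instrument noise inside the regions
    d13c[am] <- stats::runif(sum(am), -64, -51)
    dd[am] <- stats::runif(sum(am), -390, -260)
    alpha[am] <- stats::runif(sum(am), 1.0415, 1.0535)
    d13c[!am] <- stats::runif(sum(!am), -105, -66)
    dd[!am] <- stats::runif(sum(!am), -240, -160)
    alpha[!am] <- stats::runif(sum(!am), 1.0565, 1.0885)
    d13c_co2 <- alpha * (d13c + 1000) - 1000
    o2 <- numeric(n)
    for (ty in unique(types)) {
      i <- types == ty
      o2[i] <- runif_range(sum(i), config$o2_range[[ty]])
    }
    d13c_obs <- d13c + config$oxidation_slope * (o2 - mean(o2)) +
      stats::rnorm(n, 0, config$d13c_noise)
    data.frame(
      pond_id = pond_ids, transport = transport,
      d13c_ch4 = d13c_obs,
      dd_ch4 = dd + stats::rnorm(n, 0, config$dd_noise),
      d13c_co2 = d13c_co2 + stats::rnorm(n, 0, config$d13c_noise),
      o2_mgL = o2,
      true_pathway = pathway, true_alpha_c = alpha
    )
  }
  for (transport in c("diffusion", "ebullition")) {
    counts <- if (transport == "diffusion") config$n_iso_diffusion
              else config$n_iso_ebullition
    for (ty in names(counts)) {
      ids <- ponds$pond_id[ponds$type == ty][seq_len(counts[[ty]])]
      if (length(ids)) {
        iso_rows[[length(iso_rows) + 1L]] <-
          draw_iso(ids, rep(ty, length(ids)), transport)
      }
    }
  }
  iso_full <- do.call(rbind, iso_rows)
  iso_full$sample_id <- sprintf("ISO%03d", seq_len(nrow(iso_full)))
  isotopes <- iso_full[c("sample_id", "pond_id", "transport", "d13c_ch4",
                         "dd_ch4", "d13c_co2", "o2_mgL")]
  truth_iso <- iso_full[c("sample_id", "pond_id", "transport",
                          "true_pathway", "true_alpha_c")]

  # --- radiocarbon ---------------------------------------------------------
  c14_rows <- list()
  for (ty in names(config$n_c14)) {
    n <- config$n_c14[[ty]]
    if (n < 1) next
    ids <- sample(ponds$pond_id[ponds$type == ty], n, replace = TRUE)
    f_old <- runif_range(n, config$f_old_range[[ty]])
    fm <- config$endmembers$modern_fm -
      f_old * (config$endmembers$modern_fm - config$endmembers$old_fm)
    d14c <- fm_to_delta14c(fm, config$c14_year) +
      stats::rnorm(n, 0, config$c14_noise_permil)
    c14_rows[[ty]] <- data.frame(
      pond_id = ids,
      species = sample(c("CH4", "CO2"), n, replace = TRUE),
      transport = "ebullition",
      delta14c_permil = d14c,
      year = config$c14_year,
      true_f_old = f_old, true_fm = fm
    )
  }
  c14_full <- do.call(rbind, c14_rows)
  rownames(c14_full) <- NULL
  c14_full$sample_id <- sprintf("C14-%02d", seq_len(nrow(c14_full)))
  radiocarbon <- c14_full[c("sample_id", "pond_id", "species", "transport",
                            "delta14c_permil", "year")]
  truth_c14 <- c14_full[c("sample_id", "pond_id", "true_f_old", "true_fm")]

  structure(list(
    config = config,
    ponds = ponds,
    wind = wind,
    headspace = headspace,
    funnels = funnels,
    isotopes = isotopes,
    radiocarbon = radiocarbon,
    truth = list(
      dissolved = do.call(rbind, truth_diss),
      flux = do.call(rbind, truth_flux),
      ebullition = truth_ebul,
      isotopes = truth_iso,
      radiocarbon = truth_c14
    )
  ), class = "pond_campaign")
}

#' Write a campaign to a directory of CSV files
#'
#' Emits `ponds.csv`, `wind.csv`, `headspace.csv`, `funnels.csv`,
#' `isotopes.csv`, `radiocarbon.csv`, a single long-format
#' `ground_truth.csv` (columns `table`, `row`, `variable`, `value`) and a
#' `manifest.txt` recording the seed, the package version and the scalar
#' configuration.
#'
#' @param campaign From [generate_campaign()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("ponds", "wind", "headspace", "funnels", "isotopes", "radiocarbon")
  for (tb in tabs) {
    df <- campaign[[tb]]
    if (tb == "wind") df$timestamp <- format(df$timestamp, "%Y-%m-%d %H:%M:%S")
    utils::write.csv(df, file.path(dir, paste0(tb, ".csv")), row.names = FALSE)
  }
  gt <- do.call(rbind, lapply(names(campaign$truth), function(nm) {
    df <- campaign$truth[[nm]]
    num <- names(df)[vapply(df, is.numeric, logical(1))]
    key <- do.call(paste, c(df[setdiff(names(df), num)], sep = "|"))
    do.call(rbind, lapply(num, function(v) {
      data.frame(table = nm, row = key, variable = v, value = df[[v]])
    }))
  }))
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  cfg <- campaign$config
  scalars <- cfg[vapply(cfg, function(x) is.atomic(x) && length(x) <= 2,
                        logical(1))]
  writeLines(c(
    paste0("package: pondgas ",
           as.character(utils::packageVersion("pondgas"))),
    paste0("seed: ", cfg$seed),
    vapply(names(scalars), function(nm) {
      paste0(nm, ": ", paste(format(scalars[[nm]]), collapse = ", "))
    }, character(1))
  ), file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a campaign directory written by [write_campaign()]
#'
#' @param dir Campaign directory.
#' @return list with the six observational tables (`wind` timestamps parsed)
#'   and `ground_truth` in long format.
#' @export
read_campaign <- function(dir) {
  out <- list(
    ponds = read_table_csv(file.path(dir, "ponds.csv"),
                           c("pond_id", "type")),
    wind = read_wind_csv(file.path(dir, "wind.csv")),
    headspace = read_headspace_csv(file.path(dir, "headspace.csv")),
    funnels = read_funnel_csv(file.path(dir, "funnels.csv")),
    isotopes = read_isotope_csv(file.path(dir, "isotopes.csv")),
    radiocarbon = read_radiocarbon_csv(file.path(dir, "radiocarbon.csv"))
  )
  gt_path <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt_path)) {
    out$ground_truth <- utils::read.csv(gt_path, stringsAsFactors = FALSE)
  }
  out
}
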