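test_that("lognormal moment matching is exact in closed form", {
  p <- lognormal_from_mean_sd(119, 124)
  # analytic mean and sd of the fitted lognormal reproduce the inputs
  m <- exp(p$meanlog + p$sdlog^2 / 2)
  s <- m * sqrt(exp(p$sdlog^2) - 1)
  expect_equal(m, 119, tolerance = 1e-12)
  expect_equal(s, 124, tolerance = 1e-12)
  # sd = 0 degenerates to a point mass
  p0 <- lognormal_from_mean_sd(4.1, 0)
  expect_equal(p0$sdlog, 0)
  expect_equal(exp(p0$meanlog), 4.1)
  # large-sample draws converge to the configured moments
  set.seed(8)
  x <- rlnorm(1e6, p$meanlog, p$sdlog)
  expect_equal(mean(x), 119, tolerance = 0.01)
  expect_equal(sd(x), 124, tolerance = 0.01)
  expect_error(lognormal_from_mean_sd(0, 1), "mean")
})

test_that("identical seeds give byte-identical campaigns", {
  cfg <- campaign_config(n_polygonal = 6, n_runnel = 8, seed = 99,
                         n_iso_diffusion = c(polygonal = 3, runnel = 3),
                         n_c14 = c(polygonal = 3, runnel = 2))
  c1 <- generate_campaign(cfg)
  c2 <- generate_campaign(cfg)
  expect_identical(c1, c2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_campaign(c1, d1)
  write_campaign(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f))[-1],
                     readLines(file.path(d2, f))[-1])
  }
  # a different seed changes the draws
  c3 <- generate_campaign(campaign_config(n_polygonal = 6, n_runnel = 8,
                                          seed = 100,
                                          n_iso_diffusion = c(polygonal = 3,
                                                              runnel = 3),
                                          n_c14 = c(polygonal = 3,
                                                    runnel = 2)))
  expect_false(identical(c1$headspace$ppm_final, c3$headspace$ppm_final))
})

test_that("campaign tables have the documented structure and ranges", {
  cfg <- campaign_config(n_polygonal = 5, n_runnel = 7, seed = 2,
                         n_iso_diffusion = c(polygonal = 4, runnel = 4),
                         n_c14 = c(polygonal = 4, runnel = 3))
  camp <- generate_campaign(cfg)
  expect_equal(nrow(camp$ponds), 12)
  expect_equal(sum(camp$ponds$type == "runnel"), 7)
  expect_equal(nrow(camp$headspace), 24)  # two species per pond
  expect_true(all(camp$funnels$ch4_frac >= 0.015 &
                  camp$funnels$ch4_frac <= 0.32))
  expect_true(all(camp$truth$ebullition$flux_mmol_m2_d <= 2.13))
  expect_true(all(camp$wind$u10_ms > 0))
  # every observational row traces to a ground-truth row
  expect_setequal(camp$isotopes$sample_id, camp$truth$isotopes$sample_id)
  expect_setequal(camp$radiocarbon$sample_id,
                  camp$truth$radiocarbon$sample_id)
  expect_setequal(
    paste(camp$headspace$pond_id, camp$headspace$species),
    paste(camp$truth$dissolved$pond_id, camp$truth$dissolved$species))
})

test_that("group concentration moments converge to the configured values", {
  # many campaigns: empirical runnel/polygonal CH4 mean ratio approaches
  # the configured 4.1/1.3
  means_r <- means_p <- numeric(120)
  for (i in seq_len(120)) {
    cfg <- campaign_config(n_polygonal = 12, n_runnel = 12, seed = 5000 + i,
                           n_c14 = c(polygonal = 2, runnel = 2))
    camp <- generate_campaign(cfg)
    tr <- camp$truth$dissolved
    ch4 <- tr[tr$species == "CH4", ]
    ty <- camp$ponds$type[match(ch4$pond_id, camp$ponds$pond_id)]
    means_r[i] <- mean(ch4$conc_uM[ty == "runnel"])
    means_p[i] <- mean(ch4$conc_uM[ty == "polygonal"])
  }
  ratio <- mean(means_r) / mean(means_p)
  expect_equal(ratio, 4.1 / 1.3, tolerance = 0.15)
})

test_that("campaign round-trips through the CSV directory", {
  cfg <- campaign_config(n_polygonal = 4, n_runnel = 4, seed = 17,
                         n_iso_diffusion = c(polygonal = 2, runnel = 2),
                         n_iso_ebullition = c(polygonal = 1, runnel = 1),
                         n_c14 = c(polygonal = 2, runnel = 2))
  camp <- generate_campaign(cfg)
  dir <- withr::local_tempdir()
  write_campaign(camp, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "ponds.csv", "wind.csv", "headspace.csv", "funnels.csv",
    "isotopes.csv", "radiocarbon.csv", "ground_truth.csv",
    "manifest.txt")))))
  back <- read_campaign(dir)
  expect_equal(back$headspace$ppm_final, camp$headspace$ppm_final)
  expect_equal(back$wind$u10_ms, camp$wind$u10_ms)
  expect_s3_class(back$wind$timestamp, "POSIXct")
  # reports from the in-memory and on-disk campaigns agree
  r1 <- run_report(camp)
  r2 <- run_report(dir)
  expect_equal(r2$dissolved$conc_uM, r1$dissolved$conc_uM)
  expect_equal(r2$fluxes$flux_mmol_m2_d, r1$fluxes$flux_mmol_m2_d)
})

test_that("config validation rejects inconsistent settings before generation", {
  expect_error(campaign_config(n_polygonal = 0), "counts")
  expect_error(campaign_config(gc_noise_cv = -0.1), "noise")
  expect_error(campaign_config(bubble_ch4_range = c(0.5, 1.5)), "bubble")
  expect_error(campaign_config(nonsense = 1), "unknown config field")
  cfg <- campaign_config()
  cfg$conc$CH4$runnel[["mean"]] <- -1
  expect_error(generate_campaign(cfg), "concentration mean")
})
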