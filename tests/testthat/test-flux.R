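test_that("k600 wind model evaluates correctly and increases with wind", {
  expect_equal(k600_cole(0), 2.07)
  expect_equal(k600_cole(5), 2.07 + 0.215 * 5^1.7, tolerance = 1e-12)
  u <- seq(0, 15, by = 0.1)
  expect_true(all(diff(k600_cole(u)) > 0))
  expect_error(k600_cole(-0.1), "u10")
})

test_that("wind window mean filters the preceding interval", {
  t0 <- as.POSIXct("2011-07-01 12:00:00", tz = "UTC")
  wind <- data.frame(
    timestamp = t0 + seq(-6 * 3600, 0, by = 1800),
    u10_ms = 5
  )
  expect_equal(wind_window_mean(wind, t0), 5)

  wind$u10_ms <- seq_along(wind$u10_ms)  # irregular values
  # brute-force filter-and-average oracle
  inside <- wind$timestamp >= t0 - 2 * 3600 & wind$timestamp <= t0
  expect_equal(wind_window_mean(wind, t0, 2), mean(wind$u10_ms[inside]))

  two <- data.frame(timestamp = t0 - c(3600, 1800), u10_ms = c(2, 4))
  expect_equal(wind_window_mean(two, t0), 3)

  expect_error(wind_window_mean(two, t0 + 10 * 3600), "no wind observations")
})

test_that("transfer velocity applies the Schmidt exponent convention", {
  # normalisation point: Sc = 600 gives k600 x 0.24 for either exponent
  expect_equal(transfer_velocity(2.07, 600, 1), 2.07 * 0.24)
  expect_equal(transfer_velocity(2.07, 600, 8), 2.07 * 0.24)

  # hand evaluation above the wind threshold
  expect_equal(transfer_velocity(2.07, 1200, 5),
               2.07 * 2^(-1 / 2) * 0.24, tolerance = 1e-12)
  # below threshold, exponent 2/3
  expect_equal(transfer_velocity(2.07, 1200, 1),
               2.07 * 2^(-2 / 3) * 0.24, tolerance = 1e-12)
  # boundary at exactly 3 m s-1 uses 1/2
  expect_equal(transfer_velocity(2.07, 1200, 3),
               transfer_velocity(2.07, 1200, 5))
  # k decreases with Schmidt number
  sc <- seq(300, 1500, by = 50)
  expect_true(all(diff(transfer_velocity(2.07, sc, 5)) < 0))
  expect_error(transfer_velocity(2.07, 0, 5), "schmidt")
})

test_that("equilibrium concentration tracks solubility and mixing ratio", {
  co2 <- gas_species("CO2")
  expect_equal(equilibrium_concentration(co2, 10, mixing_ratio_ppm = 0), 0)
  expect_gt(equilibrium_concentration(co2, 5), equilibrium_concentration(co2, 20))
  expect_equal(equilibrium_concentration(co2, 10),
               oracle_kh(3.4e-2, 2400, 10) * 390e-6 * 1e6, tolerance = 1e-12)
})

test_that("diffusive flux obeys the sign convention and worked arithmetic", {
  ch4 <- gas_species("CH4")
  co2 <- gas_species("CO2")

  expect_equal(diffusive_flux(ch4, 5, 5, k = 0.3)$flux_mmol_m2_d, 0)

  fx <- diffusive_flux(ch4, 4.1, 0.004, k = 0.351, correction = 0.2458)
  expect_equal(fx$flux_mmol_m2_d, 0.2458 * 0.351 * (4.1 - 0.004),
               tolerance = 1e-12)

  # undersaturated CO2 (polygonal-pond conditions): uptake, negative flux
  c_eq <- equilibrium_concentration(co2, 10)
  fx <- diffusive_flux(co2, 9.6, c_eq, k = 0.3)
  expect_lt(fx$flux_mmol_m2_d, 0)

  # linear in the gradient and in the correction factor
  f1 <- diffusive_flux(ch4, 3, 1, k = 0.3, correction = 0.2458)$flux_mmol_m2_d
  f2 <- diffusive_flux(ch4, 5, 1, k = 0.3, correction = 0.2458)$flux_mmol_m2_d
  expect_equal(f2 / f1, (5 - 1) / (3 - 1))
  f3 <- diffusive_flux(ch4, 3, 1, k = 0.3, correction = 0.4916)$flux_mmol_m2_d
  expect_equal(f3, 2 * f1)

  expect_error(diffusive_flux(ch4, 3, 1, k = 0), "k must be")
  expect_error(diffusive_flux(ch4, 3, 1, k = 0.3, correction = 0), "correction")
})

test_that("ebullition flux matches the ideal-gas hand calculation", {
  # 10 mL pure CH4 over 24 h at 10 degC through a 0.3526 m2 funnel
  hand <- 0.010 / (0.3526 * (0.082057338 * 283.15)) * 1000
  expect_equal(ebullition_flux(10, 24, 1, 10), hand, tolerance = 1e-9)
  expect_equal(ebullition_flux(0, 24, 0.2, 10), 0)
  # halving the CH4 fraction halves the flux
  expect_equal(ebullition_flux(10, 24, 0.5, 10),
               ebullition_flux(10, 24, 1, 10) / 2)
  # splitting one collection into consecutive sub-collections is invariant
  whole <- ebullition_flux(12, 30, 0.2, 8)
  parts <- c(ebullition_flux(4, 10, 0.2, 8), ebullition_flux(8, 20, 0.2, 8))
  expect_equal(whole, sum(parts * c(10, 20) / 30))
  expect_error(ebullition_flux(10, 0, 1, 10), "duration")
  expect_error(ebullition_flux(10, 24, 1.2, 10), "ch4_fraction")
})

test_that("correction-factor fit recovers exact and noisy proportionality", {
  m <- c(1, 2, 3, 5, 8)
  fit <- fit_correction_factor(0.5 * m, m)
  expect_equal(fit$factor, 0.5, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit_correction_factor(m, m)$factor, 1)

  # scale equivariance
  set.seed(3)
  ch <- 0.3 * m + rnorm(5, 0, 0.05)
  expect_equal(fit_correction_factor(3 * ch, m)$factor,
               3 * fit_correction_factor(ch, m)$factor)

  # agrees with the lm origin-fit oracle
  oracle <- lm(ch ~ 0 + m)
  expect_equal(fit_correction_factor(ch, m)$factor,
               unname(coef(oracle)), tolerance = 1e-12)
  expect_equal(fit_correction_factor(ch, m)$r2,
               summary(oracle)$r.squared, tolerance = 1e-12)

  # intercept mode matches lm with intercept
  fit_i <- fit_correction_factor(ch, m, intercept = TRUE)
  oracle_i <- lm(ch ~ m)
  expect_equal(fit_i$factor, unname(coef(oracle_i)[2]), tolerance = 1e-12)

  expect_error(fit_correction_factor(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_correction_factor(c(1, 2, 3), c(0, 0, 0)), "singular")
})

test_that("diurnal variation is a scale-invariant CV with a range option", {
  expect_equal(diurnal_variation(rep(4, 5)), 0)
  x <- c(1, 1, 4)
  expect_equal(diurnal_variation(x), 100 * sd(x) / mean(x))
  expect_equal(diurnal_variation(3.7 * x), diurnal_variation(x))
  expect_equal(diurnal_variation(x, method = "range"),
               100 * (4 - 1) / mean(x))
  expect_error(diurnal_variation(c(1, 2)), "3 points")
  expect_error(diurnal_variation(c(-1, -2, -3)), "mean")
})
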