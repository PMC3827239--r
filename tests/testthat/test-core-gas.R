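test_that("Henry constant follows the van 't Hoff form and its oracle", {
  co2 <- gas_species("CO2")
  ch4 <- gas_species("CH4")

  # reference-temperature identity
  expect_equal(henry_constant(co2, 25), co2$kh_ref)

  # exothermic dissolution: solubility decreases with temperature
  expect_gt(henry_constant(ch4, 5), henry_constant(ch4, 25))
  grid <- seq(-1, 39, by = 0.5)
  expect_true(all(diff(henry_constant(co2, grid)) < 0))

  # independent hand evaluation at 10 degC
  expect_equal(henry_constant(co2, 10),
               oracle_kh(3.4e-2, 2400, 10), tolerance = 1e-12)

  expect_error(henry_constant(co2, -5), "temperature")
  expect_error(henry_constant(co2, 45), "temperature")
})

test_that("dissolved concentration is Henry-linear in partial pressure", {
  co2 <- gas_species("CO2")
  expect_equal(dissolved_at_partial_pressure(co2, 15, 0), 0)
  c1 <- dissolved_at_partial_pressure(co2, 15, 390e-6)
  c2 <- dissolved_at_partial_pressure(co2, 15, 780e-6)
  expect_equal(c2, 2 * c1)
  expect_equal(c1, oracle_kh(3.4e-2, 2400, 15) * 390e-6 * 1e6,
               tolerance = 1e-12)
  expect_error(dissolved_at_partial_pressure(co2, 15, -1e-6), "partial_pressure")
})

test_that("headspace inversion recovers the oracle-equilibrated truth", {
  set.seed(42)
  for (sp in list(gas_species("CO2"), gas_species("CH4"))) {
    for (rep in 1:50) {
      cs <- random_headspace_case(sp)
      kh <- henry_constant(sp, cs$temp)
      ppm_eq <- oracle_equilibrate_ppm(kh, cs$c0, cs$vw, cs$vh, cs$temp,
                                       cs$ppm_air)
      res <- headspace_to_dissolved(sp, cs$vw, cs$vh, cs$temp,
                                    ppm_final = ppm_eq, ppm_air = cs$ppm_air)
      expect_true(res$valid)
      expect_lt(abs(res$conc_uM - cs$c0) / cs$c0, 1e-9)
    }
  }
})

test_that("headspace limiting cases and invalid readings behave", {
  ch4 <- gas_species("CH4")
  kh <- henry_constant(ch4, 12)

  # water at atmospheric equilibrium: no net transfer, C0 = KH * p_air
  res <- headspace_to_dissolved(ch4, 2, 0.02, 12,
                                ppm_final = 1.8, ppm_air = 1.8)
  expect_equal(res$conc_uM, kh * 1.8e-6 * 1e6, tolerance = 1e-12)

  # vanishing headspace: mass-balance term disappears
  res <- headspace_to_dissolved(ch4, 2, 1e-9, 12,
                                ppm_final = 500, ppm_air = 1.8)
  expect_equal(res$conc_uM, kh * 500e-6 * 1e6, tolerance = 1e-6)

  # henry_only mode drops the headspace term entirely
  res <- headspace_to_dissolved(ch4, 2, 0.02, 12, ppm_final = 500,
                                ppm_air = 1.8, method = "henry_only")
  expect_equal(res$conc_uM, kh * 500e-6 * 1e6, tolerance = 1e-12)

  # inconsistent readings (headspace depleted below any possible start)
  co2 <- gas_species("CO2")
  res <- headspace_to_dissolved(co2, 0.05, 1, 12,
                                ppm_final = 1, ppm_air = 390)
  expect_false(res$valid)
  expect_lt(res$conc_uM, 0)  # negative value carried, not clamped

  expect_error(headspace_to_dissolved(co2, -1, 0.02, 12, 400, 390), "volume")
  expect_error(headspace_to_dissolved(co2, 2, 0.02, 12, 400, 390,
                                      pressure_atm = 1.5), "pressure")
})

test_that("Schmidt polynomial is positive, decreasing, and near 600 for CO2 at 20 degC", {
  co2 <- gas_species("CO2")
  ch4 <- gas_species("CH4")
  expect_gt(schmidt_number(co2, 20), 599)
  expect_lt(schmidt_number(co2, 20), 601)
  # hand evaluation of the CH4 polynomial
  cf <- ch4$schmidt_coeffs
  expect_equal(schmidt_number(ch4, 20),
               cf[1] + cf[2] * 20 + cf[3] * 400 + cf[4] * 8000)
  grid <- seq(0, 30, by = 0.25)
  for (sp in list(co2, ch4)) {
    sc <- schmidt_number(sp, grid)
    expect_true(all(sc > 0))
    expect_true(all(diff(sc) < 0))
  }
  expect_gt(schmidt_number(co2, 5), schmidt_number(co2, 25))
  expect_error(schmidt_number(co2, -1), "temperature")
})

test_that("molar volume matches the ideal-gas reference points", {
  expect_equal(molar_volume(0, 1), 22.414, tolerance = 1e-3)
  expect_equal(molar_volume(10, 1), 22.414 * 283.15 / 273.15,
               tolerance = 1e-3)
  tt <- seq(-20, 30, by = 1)
  expect_true(all(diff(molar_volume(tt, 1)) > 0))
  expect_error(molar_volume(10, 0), "pressure")
})

test_that("gas constants are configurable and round-trip through the text file", {
  cst <- gas_constants(list(CO2 = list(atm_mixing_ratio = 400)))
  expect_equal(cst$CO2$atm_mixing_ratio, 400)
  expect_equal(cst$CH4$kh_ref, 1.4e-3)
  expect_error(gas_constants(list(N2O = list(kh_ref = 1))), "unknown")

  path <- withr::local_tempfile(fileext = ".cfg")
  write_gas_constants(cst, path)
  back <- read_gas_constants(path)
  expect_equal(back$CO2$atm_mixing_ratio, 400)
  expect_equal(back$CH4$schmidt_coeffs, cst$CH4$schmidt_coeffs)
})

test_that("table-level dissolved computation handles mixed species and flags", {
  hs <- data.frame(
    pond_id = c("A", "A", "B"),
    species = c("CO2", "CH4", "CH4"),
    water_volume_L = 2, headspace_volume_mL = 20,
    temp_C = c(10, 10, 15),
    ppm_final = c(2000, 120, 60),
    ppm_air = c(390, 1.8, 1.8)
  )
  out <- dissolved_from_headspace(hs)
  expect_equal(nrow(out), 3)
  expect_true(all(out$valid))
  one <- headspace_to_dissolved(gas_species("CH4"), 2, 0.02, 15, 60, 1.8)
  expect_equal(out$conc_uM[3], one$conc_uM)
})
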