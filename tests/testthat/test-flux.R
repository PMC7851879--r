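test_that("core flux equals slope x volume / area", {
  # +10 uM over 2 h in 0.8 L over the 8.4 cm liner area
  data <- linear_incubation("C1", "NH4", times = c(0, 2), c0 = 1, slope = 5)
  fx <- net_flux_core(data, core_geom("C1", volume_L = 0.8))
  expect_equal(fx$flux_umol_m2_h, 10 * 0.8 / (core_area(8.4) * 2),
               tolerance = 1e-12)
  expect_equal(fx$flux_umol_m2_h, 721.7, tolerance = 1e-3)
  expect_equal(fx$se, 0)

  # constant concentration: zero flux, zero SE
  flat <- net_flux_core(linear_incubation("C1", "NH4", slope = 0),
                        core_geom("C1"))
  expect_equal(flat$flux_umol_m2_h, 0)
  expect_equal(flat$se, 0)

  # sign convention: decreasing concentration = uptake = negative
  down <- net_flux_core(linear_incubation("C1", "O2", slope = -2),
                        core_geom("C1"))
  expect_lt(down$flux_umol_m2_h, 0)
})

test_that("core flux scaling contract holds", {
  data <- linear_incubation("C1", "NH4", slope = 2)
  f1 <- net_flux_core(data, core_geom("C1", volume_L = 0.8,
                                      area_m2 = 0.005))$flux_umol_m2_h
  f2 <- net_flux_core(data, core_geom("C1", volume_L = 1.6,
                                      area_m2 = 0.010))$flux_umol_m2_h
  f3 <- net_flux_core(data, core_geom("C1", volume_L = 1.6,
                                      area_m2 = 0.005))$flux_umol_m2_h
  expect_equal(f1, f2)          # doubling V and A leaves flux unchanged
  expect_equal(f3, 2 * f1)      # doubling V alone doubles it
})

test_that("oxygen drawdown beyond the quality limit is flagged, not dropped", {
  # O2 falls 25% from start over the incubation
  data <- linear_incubation("C1", "O2", times = c(0, 2, 4), c0 = 200,
                            slope = -12.5)
  fx <- net_flux_core(data, core_geom("C1"))
  expect_true(grepl("O2_DRAWDOWN_EXCEEDED", fx$qc_flags))
  expect_true(is.finite(fx$flux_umol_m2_h))

  # 15% drawdown stays unflagged
  ok <- net_flux_core(linear_incubation("C1", "O2", times = c(0, 2, 4),
                                        c0 = 200, slope = -7.5),
                      core_geom("C1"))
  expect_false(grepl("O2_DRAWDOWN_EXCEEDED", ok$qc_flags))
})

test_that("curved series get the NONLINEAR annotation", {
  t <- 0:5
  curved <- tibble::tibble(vessel_id = "C1", analyte = "NH4", time_h = t,
                           conc_uM = 10 + 0.5 * t + 2 * t^2)
  fx <- net_flux_core(curved, core_geom("C1"))
  expect_true(grepl("NONLINEAR", fx$qc_flags))
})

test_that("single sample or zero area error out", {
  one <- linear_incubation("C1", "O2", times = 0)
  expect_error(net_flux_core(one, core_geom("C1")),
               class = "iptflux_validation_error")
  expect_error(net_flux_core(linear_incubation("C1", "O2"),
                             microcosm_geom("C1")),
               class = "iptflux_validation_error")
})

test_that("microcosm rate is control-corrected and biomass-normalised", {
  # sample slope 0.01 uM/h, control flat, V = 0.227 L, W = 0.037 g
  sample <- linear_incubation("M1", "NH4", times = c(0, 3, 6, 8), c0 = 1,
                              slope = 0.01)
  control <- linear_incubation("CTRL", "NH4", times = c(0, 3, 6, 8), c0 = 1,
                               slope = 0)
  rate <- net_flux_microcosm(sample, microcosm_geom("M1"), control)
  expect_equal(rate$rate_nmol_g_h, 0.01 * 227 / 0.037, tolerance = 1e-12)
  expect_equal(rate$rate_nmol_g_h, 61.4, tolerance = 1e-2)
  expect_true(grepl("CONTROL_CORRECTED", rate$qc_flags))

  # sample slope equal to control slope: zero rate
  ctrl2 <- linear_incubation("CTRL", "NH4", times = c(0, 3, 6, 8), c0 = 2,
                             slope = 0.01)
  zero <- net_flux_microcosm(sample, microcosm_geom("M1"), ctrl2)
  expect_equal(zero$rate_nmol_g_h, 0, tolerance = 1e-12)

  # negative corrected slope is returned, not clipped
  ctrl3 <- linear_incubation("CTRL", "NH4", times = c(0, 3, 6, 8), c0 = 2,
                             slope = 0.02)
  neg <- net_flux_microcosm(sample, microcosm_geom("M1"), ctrl3)
  expect_lt(neg$rate_nmol_g_h, 0)

  # zero biomass errors
  expect_error(
    net_flux_microcosm(sample, microcosm_geom("M1", biomass_g = 0), control),
    class = "iptflux_validation_error"
  )
})

test_that("control correction is linear in the series", {
  times <- c(0, 3, 6, 8)
  sample <- linear_incubation("M1", "NH4", times = times, c0 = 1, slope = 0.05)
  control <- linear_incubation("CTRL", "NH4", times = times, c0 = 1,
                               slope = 0.02)
  geom <- microcosm_geom("M1")
  corrected <- net_flux_microcosm(sample, geom, control)$rate_nmol_g_h
  differenced <- sample |>
    dplyr::mutate(conc_uM = .data$conc_uM -
                    control$conc_uM[match(.data$time_h, control$time_h)] + 1)
  direct <- net_flux_microcosm(differenced, geom, NULL)$rate_nmol_g_h
  expect_equal(corrected, direct, tolerance = 1e-9)
})

test_that("noiseless constant production is recovered to machine precision", {
  p <- true_parameters(D_a = 100, noise_cv = 0)
  series <- simulate_15nh4_series(p)
  geom <- microcosm_geom("M1")
  rate <- production_rates(series, geom, analytes = "NH4_15N")
  expect_equal(rate$rate, p$dnra_a * p$epsilon, tolerance = 1e-10)
})

test_that("dilution correction undoes replacement-water mixing exactly", {
  geom <- microcosm_geom("M1", volume_L = 1)
  # replacement with identical concentration leaves the series unchanged
  same <- tibble::tibble(vessel_id = "M1", analyte = "NH4",
                         time_h = c(0, 1, 2), conc_uM = c(10, 10, 10))
  w_same <- tibble::tibble(vessel_id = "M1", time_h = 1,
                           volume_removed_L = 0.1, replacement_conc_uM = 10)
  expect_equal(dilution_correct(same, geom, w_same)$conc_uM, c(10, 10, 10))

  # 10% withdrawal replaced by blank water: 10 -> raw 9 reads as 10
  one <- tibble::tibble(vessel_id = "M1", analyte = "NH4",
                        time_h = c(0, 1), conc_uM = c(10, 9))
  w0 <- tibble::tibble(vessel_id = "M1", time_h = 0,
                       volume_removed_L = 0.1, replacement_conc_uM = 0)
  expect_equal(dilution_correct(one, geom, w0)$conc_uM, c(10, 10))

  # two sequential withdrawals compose exactly (mass ledger oracle)
  two <- tibble::tibble(vessel_id = "M1", analyte = "NH4",
                        time_h = c(0, 1, 2), conc_uM = c(10, 9, 8.1))
  w2 <- tibble::tibble(vessel_id = "M1", time_h = c(0, 1),
                       volume_removed_L = 0.1, replacement_conc_uM = 0)
  expect_equal(dilution_correct(two, geom, w2)$conc_uM, c(10, 10, 10))

  # production between withdrawals survives the correction
  prod <- tibble::tibble(vessel_id = "M1", analyte = "NH4",
                         time_h = c(0, 1, 2),
                         conc_uM = c(10, 9 + 0.5, 0.9 * 9.5 + 0.5))
  expect_equal(dilution_correct(prod, geom, w2)$conc_uM,
               c(10, 10.5, 11), tolerance = 1e-12)

  # withdrawal at an unsampled time errors
  w_bad <- tibble::tibble(vessel_id = "M1", time_h = 0.5,
                          volume_removed_L = 0.1, replacement_conc_uM = 0)
  expect_error(dilution_correct(one, geom, w_bad),
               class = "iptflux_validation_error")
  # withdrawal of the whole vessel errors
  w_big <- tibble::tibble(vessel_id = "M1", time_h = 0,
                          volume_removed_L = 1, replacement_conc_uM = 0)
  expect_error(dilution_correct(one, geom, w_big),
               class = "iptflux_validation_error")
})

test_that("endpoint mode uses only the first and last samples", {
  data <- tibble::tibble(vessel_id = "C1", analyte = "NH4",
                         time_h = c(0, 1, 2), conc_uM = c(0, 5, 4))
  geom <- core_geom("C1", volume_L = 1, area_m2 = 1)
  ep <- net_flux_core(data, geom, method = "endpoints")
  expect_equal(ep$flux_umol_m2_h, 2)  # (4-0)/2 * 1/1
})
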