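test_that("biomass upscaling reproduces the printed areal rates", {
  # holobiont DNRA mean x areal colony biomass
  expect_equal(areal_from_specific(31.2, 134), 4.1808, tolerance = 1e-12)
  expect_equal(areal_from_specific(31.2, 134), 4.2, tolerance = 0.01)
  expect_equal(areal_from_specific(58.4, 134), 7.8256, tolerance = 1e-12)
  expect_equal(areal_from_specific(0, 134), 0)
  # homogeneous of degree 1 in the rate
  expect_equal(areal_from_specific(2 * 31.2, 134),
               2 * areal_from_specific(31.2, 134))
})

test_that("contribution fractions match the study's ratios", {
  # fixation vs denitrification in the holobiont: ~37%
  expect_equal(contribution_fraction(21.9, 58.4), 37.5, tolerance = 1e-3)
  # upscaled DNRA vs the community increment: ~74%
  expect_equal(contribution_fraction(areal_from_specific(31.2, 134), 5.7),
               73.3, tolerance = 1e-2)
  expect_equal(contribution_fraction(5, 5), 100)
  expect_warning(out <- contribution_fraction(5, 0))
  expect_true(is.na(out))
})

test_that("ignoring fixation overestimates the net N2 flux as stated", {
  expect_equal(net_n2_overestimate(58.4, 21.9), 100 * 21.9 / 36.5,
               tolerance = 1e-12)
  expect_equal(net_n2_overestimate(58.4, 21.9), 60.0, tolerance = 1e-3)
  expect_equal(net_n2_overestimate(58.4, 0), 0)
  expect_equal(net_n2_overestimate(20, 10), 100)  # denit = 2 x fixation
  expect_warning(out <- net_n2_overestimate(10, 20))
  expect_true(is.na(out))
})

test_that("density extrapolation covers the reported abundance range", {
  scen <- density_scale(
    data.frame(density_ind_m2 = c(40, 12600, 57000)),
    specific_rate_nmol_g_h = 7.8, mean_sfdw_g = 0.037
  )
  # 7.8 nmol/g/h x 0.037 g x 40 /m2 = 0.0115 umol m-2 h-1
  expect_equal(scen$areal_umol_m2_h[1], 7.8 * 0.037 * 40 / 1000,
               tolerance = 1e-12)
  expect_equal(round(scen$areal_umol_m2_h[1], 2), 0.01)
  expect_equal(attr(scen, "summary")$min, scen$areal_umol_m2_h[1])
  # linearity in density
  expect_equal(
    density_scale(data.frame(density_ind_m2 = 80),
                  per_individual_nmol_h = 0.2886)$areal_umol_m2_h,
    2 * density_scale(data.frame(density_ind_m2 = 40),
                      per_individual_nmol_h = 0.2886)$areal_umol_m2_h
  )
  expect_equal(
    density_scale(data.frame(density_ind_m2 = 0),
                  per_individual_nmol_h = 1)$areal_umol_m2_h, 0
  )
})

test_that("budget assembly joins community and holobiont rates", {
  benthic <- tibble::tibble(
    process = c("DNRA", "DNRA", "NH4_efflux", "NH4_efflux"),
    condition = c("bare", "colonized", "bare", "colonized"),
    areal_rate_umol_m2_h = c(1.0, 6.7, -2, 20)
  )
  holo <- tibble::tibble(process = "DNRA", specific_rate_nmol_g_h = 31.2)
  b <- assemble_budget(benthic, holo, areal_biomass_g_m2 = 134)
  dnra <- b[b$process == "DNRA", ]
  expect_equal(dnra$increment, 5.7)
  expect_equal(dnra$holobiont_contribution, 4.1808)
  expect_equal(dnra$holobiont_share_pct, 100 * 4.1808 / 5.7,
               tolerance = 1e-9)
  expect_equal(dnra$flags, "")
  # input numbers are carried, never recomputed
  expect_equal(dnra$colonized, 6.7)

  # holobiont contribution larger than the colonized rate is diagnostic
  over <- assemble_budget(
    tibble::tibble(process = "DNRA", condition = "colonized",
                   areal_rate_umol_m2_h = 2),
    tibble::tibble(process = "DNRA", areal_rate_umol_m2_h = 4)
  )
  expect_equal(over$flags, "EXCEEDS")

  # empty holobiont set: community-only table
  solo <- assemble_budget(benthic)
  expect_true(all(is.na(solo$holobiont_contribution)))
  expect_error(assemble_budget(dplyr::mutate(benthic, process = "CH4_flux")),
               class = "iptflux_validation_error")
})

test_that("a self-consistent budget balances to zero residual", {
  benthic <- tibble::tibble(
    process = c("N2_fixation", "D_w", "D_n", "NH4_efflux", "NOx_efflux",
                "DON_efflux"),
    condition = "colonized",
    areal_rate_umol_m2_h = c(10, 3, 2, 4, 0.5, 0.5)
  )
  b <- assemble_budget(benthic)
  res <- attr(b, "residuals")
  expect_equal(res$residual_umol_m2_h[res$condition == "colonized"], 0)
})

test_that("budget and panel objects expose tidy views", {
  benthic <- tibble::tibble(
    process = "DNRA", condition = c("bare", "colonized"),
    areal_rate_umol_m2_h = c(1, 6.7)
  )
  long <- generics::tidy(assemble_budget(benthic))
  expect_true(all(c("quantity", "areal_rate_umol_m2_h") %in% names(long)))

  panel <- ipt_partition(
    tibble::tibble(vessel_id = "M1", p29 = 24, p30 = 18,
                   p29_p_value = 1e-3, p30_p_value = 1e-3),
    0.6
  )
  expect_equal(generics::glance(panel)$mean_D_tot, 100)
  expect_s3_class(generics::tidy(panel), "tbl_df")
})
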