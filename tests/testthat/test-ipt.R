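sig <- function(p29, p30, ...) {
  tibble::tibble(vessel_id = "M1", basis = "specific_nmol_g_h",
                 p29 = p29, p30 = p30,
                 p29_p_value = 1e-4, p30_p_value = 1e-4, ...)
}

test_that("pairing partition reproduces the binomial oracle", {
  # forward binomial pairing at D_a = 100 N atoms, eps = 0.6:
  # pairs = 50, p29 = 50*2*0.6*0.4 = 24, p30 = 50*0.36 = 18
  panel <- ipt_partition(sig(24, 18), epsilon = 0.6)
  expect_equal(panel$D15, 60)
  expect_equal(panel$D14, 40)
  expect_equal(panel$D_tot, 100)
  # sediment-free: all denitrification fuelled by water nitrate
  expect_equal(panel$D_w, 100, tolerance = 1e-12)
  expect_equal(panel$D_n, 0, tolerance = 1e-9)
})

test_that("partition identities hold exactly when nothing was floored", {
  set.seed(7)
  for (i in 1:25) {
    d <- runif(1, 10, 300); eps <- runif(1, 0.2, 0.95)
    extra14 <- runif(1, 0, 50)  # nitrification-coupled unlabelled pool
    # pairing over combined pool: labelled fraction of reduced NO3
    eps_pool <- d * eps / (d + extra14)
    pairs <- (d + extra14) / 2
    panel <- ipt_partition(
      sig(pairs * 2 * eps_pool * (1 - eps_pool), pairs * eps_pool^2),
      epsilon = eps
    )
    expect_equal(panel$D_tot, panel$D14 + panel$D15, tolerance = 0)
    if (panel$flags == "") {
      expect_equal(panel$D_w + panel$D_n, panel$D_tot, tolerance = 1e-13)
    }
    expect_equal(panel$D_tot, d + extra14, tolerance = 1e-9)
  }
})

test_that("fully labelled pool is a boundary, not a blow-up", {
  # eps = 1: no 29N2 from pairing, D14 = 0, D_tot = D15
  panel <- ipt_partition(sig(0, 30), epsilon = 1)
  expect_equal(panel$D14, 0)
  expect_equal(panel$D_tot, panel$D15)
  expect_equal(panel$D15, 60)

  # p30 <= 0 with p29 > 0: D14 undefined, flagged, no division blow-up
  und <- ipt_partition(sig(24, 0), epsilon = 0.6)
  expect_true(grepl("UNDEFINED_D14", und$flags))
  expect_equal(und$D15, 24)
  expect_true(is.na(und$D14))

  expect_error(ipt_partition(sig(24, 18), epsilon = 0),
               class = "iptflux_validation_error")
})

test_that("non-significant panels are zeroed with a flag, not dropped", {
  ns <- tibble::tibble(vessel_id = "M1", basis = NA_character_,
                       p29 = 24, p30 = 18,
                       p29_p_value = 0.4, p30_p_value = 0.01)
  panel <- ipt_partition(ns, epsilon = 0.6, alpha = 0.05)
  expect_false(panel$significant)
  expect_true(grepl("NOT_SIGNIFICANT", panel$flags))
  expect_equal(panel$D_tot, 0)
  expect_equal(nrow(panel), 1)

  # pooled gate overrides per-row p-values
  pooled <- ipt_partition(ns, epsilon = 0.6, alpha = 0.05, gate_p = 0.001)
  expect_true(pooled$significant)
  expect_equal(pooled$D_tot, 100)
})

test_that("noiseless simulated series recover the generated slopes", {
  p <- true_parameters(D_a = 100, noise_cv = 0)
  geom <- microcosm_geom("M1")
  iso <- isotopologue_slopes(simulate_n2_series(p), geom)
  pairs <- 100 / 2
  expect_equal(iso$p28, pairs * 0.4^2, tolerance = 1e-9)
  expect_equal(iso$p29, pairs * 2 * 0.6 * 0.4, tolerance = 1e-9)
  expect_equal(iso$p30, pairs * 0.6^2, tolerance = 1e-9)
  # flat series: rate 0, p ~ 1
  p0 <- true_parameters(D_a = 0, dnra_a = 0, noise_cv = 0)
  iso0 <- isotopologue_slopes(simulate_n2_series(p0), geom)
  expect_equal(iso0$p29, 0, tolerance = 1e-12)
  expect_equal(iso0$p29_p_value, 1)
  # partition of the recovered rates returns D_a on the specific basis
  panel <- ipt_partition(iso, 0.6)
  expect_equal(panel$D_tot, 100, tolerance = 1e-9)
})

test_that("pairing consistency is 1 for pure pairing, > 1 with anammox", {
  p_pure <- true_parameters(D_a = 100, amx_a = 0, noise_cv = 0)
  p_amx <- true_parameters(D_a = 100, amx_a = 20, noise_cv = 0)
  geom <- microcosm_geom("M1")
  r_pure <- pairing_consistency(
    isotopologue_slopes(simulate_n2_series(p_pure), geom))
  r_amx <- pairing_consistency(
    isotopologue_slopes(simulate_n2_series(p_amx), geom))
  expect_equal(r_pure$pairing_ratio, 1, tolerance = 1e-8)
  expect_gt(r_amx$pairing_ratio, 1)
})

test_that("independence check compares mean rates at the stated tolerance", {
  mk <- function(dtot) {
    tibble::tibble(vessel_id = "M1", D_tot = dtot, significant = TRUE)
  }
  same <- independence_check(mk(100), mk(100))
  expect_true(same$pass)
  expect_equal(same$ratio, 1)

  apart <- independence_check(mk(100), mk(140), tol = 0.25)
  expect_false(apart$pass)
  expect_equal(apart$rel_diff, 40 / 120, tolerance = 1e-12)

  # non-significant panels are excluded; empty side skips the check
  skipped <- independence_check(
    tibble::tibble(vessel_id = "M1", D_tot = 0, significant = FALSE),
    mk(100)
  )
  expect_true(skipped$skipped)
  expect_true(is.na(skipped$pass))
})

test_that("D_tot is tracer-independent under pure denitrification", {
  geom <- microcosm_geom("M1")
  dtots <- vapply(c(0.3, 0.6, 0.9), function(eps) {
    p <- true_parameters(D_a = 100, epsilon = eps, noise_cv = 0)
    panel <- ipt_partition(isotopologue_slopes(simulate_n2_series(p), geom),
                           eps)
    panel$D_tot
  }, numeric(1))
  expect_equal(dtots, rep(100, 3), tolerance = 1e-8)
})

test_that("anammox estimator scales 29N2 production by the NH4 labelling", {
  # p29 = 1 at f_a = 0.5: 2 N2 pairs / h, 4 N atoms / h
  r <- tibble::tibble(vessel_id = "M1", p29 = 1, p30 = 0,
                      p29_p_value = 0.001)
  a <- anammox_rate(r, f_a = 0.5)
  expect_equal(a$amx_n2_pairs, 2)
  expect_equal(a$amx_n_atoms, 4)
  expect_true(a$detected)

  # no 29N2 production: not detected, rate 0
  none <- anammox_rate(dplyr::mutate(r, p29 = 0, p29_p_value = 0.9), 0.5)
  expect_false(none$detected)
  expect_equal(none$amx_n_atoms, 0)

  expect_error(anammox_rate(r, f_a = 0), class = "iptflux_validation_error")
})

test_that("injected anammox is recovered from the 15NH4+ treatment", {
  geom <- microcosm_geom("M1")
  p <- true_parameters(D_a = 100, amx_a = 20, noise_cv = 0)
  iso <- isotopologue_slopes(simulate_n2_series(p, treatment = "nh4"), geom)
  a <- anammox_rate(iso, f_a = p$f_a)
  expect_true(a$detected)
  expect_equal(a$amx_n_atoms, 20, tolerance = 1e-8)
  # the 15NH4+ treatment produces no 30N2
  expect_equal(iso$p30, 0, tolerance = 1e-10)
})
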