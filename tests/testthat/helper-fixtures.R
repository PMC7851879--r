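# Shared in-code fixtures: tiny vessels and noiseless series built from
# first principles so every expected value is hand-checkable.

microcosm_geom <- function(vessel_ids = "M1", volume_L = 0.227,
                           biomass_g = 0.037) {
  tibble::tibble(
    vessel_id = vessel_ids, kind = "microcosm",
    water_volume_L = volume_L, sediment_area_m2 = NA_real_,
    biomass_g = biomass_g
  )
}

core_geom <- function(vessel_ids = "C1", volume_L = 0.8,
                      area_m2 = core_area(8.4)) {
  tibble::tibble(
    vessel_id = vessel_ids, kind = "core",
    water_volume_L = volume_L, sediment_area_m2 = area_m2,
    biomass_g = 0
  )
}

# one analyte, linear in time: conc = c0 + slope * t
linear_incubation <- function(vessel_id = "C1", analyte = "O2",
                              times = c(0, 2, 4), c0 = 250, slope = 0) {
  tibble::tibble(
    vessel_id = vessel_id, analyte = analyte, time_h = times,
    conc_uM = c0 + slope * times
  )
}

# brute-force exact two-sided Mann-Whitney p by explicit loop over all
# arrangements -- written independently of the package's vectorised
# counting so it can serve as an enumeration oracle
brute_force_mw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  sets <- utils::combn(n, n1, simplify = FALSE)
  u_all <- vapply(sets, u_of, numeric(1))
  p_low <- sum(u_all <= u_obs + 1e-9) / length(u_all)
  p_high <- sum(u_all >= u_obs - 1e-9) / length(u_all)
  min(1, 2 * min(p_low, p_high))
}
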