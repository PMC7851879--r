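#' Ground-truth parameters for the incubation simulator
#'
#' Collects the true process rates and labelling conditions from which
#' the forward simulator generates incubation datasets. Defaults emulate
#' the holobiont study conditions: biomass-specific rates on the scale
#' of the reported means (denitrification 58.4, DNRA 31.2, fixation
#' 21.9 nmol N g-1 h-1), a 15NO3- labelling fraction of 0.6, a 227 mL
#' microcosm holding a 37 mg SFDW animal, and sampling at 0, 3, 6 h and
#' termination (8 h). Measurement noise is i.i.d. Gaussian on
#' concentrations with SD equal to `noise_cv` times the net signal range
#' of each analyte (5% CV by default); rates themselves carry no process
#' error, matching the linear-accumulation assumption of the analysis.
#'
#' @param D_a True denitrification rate (N atoms; nmol g-1 h-1 for
#'   microcosms, umol m-2 h-1 for cores).
#' @param dnra_a True DNRA rate (same basis).
#' @param amx_a True anammox rate (N atoms, same basis).
#' @param fix_a True N2 fixation rate (nmol N g-1 h-1).
#' @param epsilon 15N fraction of the NO3- pool after tracer addition.
#' @param f_a 15N fraction of the NH4+ pool in the ammonium-labelled
#'   treatment (default 0.85: a 6.3 uM addition into ~1 uM ambient).
#' @param a_n2_source Atom% 15N of the dissolved N2 pool in the fixation
#'   incubations (default 50: the microcosms are filled entirely from a
#'   30N2-enriched stock water).
#' @param noise_cv Measurement noise as a fraction of each analyte's net
#'   concentration change (default 0.05).
#' @param noise_sd Optional named vector of absolute noise SDs (uM),
#'   overriding `noise_cv` for the named analytes.
#' @param schedule Sampling times (h), strictly increasing.
#' @param vessel List with `kind`, `water_volume_L`, `sediment_area_m2`,
#'   `biomass_g` (defaults: the study's microcosm).
#' @param baseline_n2_uM Ambient dissolved N2 (uM; default 470,
#'   air-equilibrated freshwater at 23 C) split into isotopologues at
#'   natural abundance.
#' @param seed Integer RNG seed.
#' @return A list of class `iptflux_params`.
#' @export
true_parameters <- function(D_a = 58.4, dnra_a = 31.2, amx_a = 0,
                            fix_a = 21.9, epsilon = 0.6, f_a = 0.85,
                            a_n2_source = 50, noise_cv = 0.05,
                            noise_sd = NULL,
                            schedule = c(0, 3, 6, 8),
                            vessel = list(kind = "microcosm",
                                          water_volume_L = 0.227,
                                          sediment_area_m2 = NA_real_,
                                          biomass_g = 0.037),
                            baseline_n2_uM = 470,
                            seed = 1L) {
  stopifnot(
    D_a >= 0, dnra_a >= 0, amx_a >= 0, fix_a >= 0,
    epsilon >= 0, epsilon <= 1, f_a >= 0, f_a <= 1,
    a_n2_source >= 0, a_n2_source <= 100,
    noise_cv >= 0, length(schedule) >= 2, all(diff(schedule) > 0),
    vessel$water_volume_L > 0
  )
  structure(
    list(D_a = D_a, dnra_a = dnra_a, amx_a = amx_a, fix_a = fix_a,
         epsilon = epsilon, f_a = f_a, a_n2_source = a_n2_source,
         noise_cv = noise_cv, noise_sd = noise_sd, schedule = schedule,
         vessel = vessel, baseline_n2_uM = baseline_n2_uM,
         seed = as.integer(seed)),
    class = "iptflux_params"
  )
}

# rate (specific or areal) -> concentration slope in uM/h
rate_to_slope <- function(rate, vessel) {
  if (vessel$kind == "core") {
    rate * vessel$sediment_area_m2 / vessel$water_volume_L
  } else {
    rate * vessel$biomass_g / (1000 * vessel$water_volume_L)
  }
}

noise_for <- function(p, analyte, slope) {
  if (!is.null(p$noise_sd) && analyte %in% names(p$noise_sd)) {
    return(p$noise_sd[[analyte]])
  }
  p$noise_cv * abs(slope) * diff(range(p$schedule))
}

linear_series <- function(p, vessel_id, analyte, baseline, slope) {
  sd_i <- noise_for(p, analyte, slope)
  conc <- baseline + slope * p$schedule +
    if (sd_i > 0) rnorm(length(p$schedule), 0, sd_i) else 0
  tibble(vessel_id = vessel_id, analyte = analyte,
         time_h = p$schedule, conc_uM = pmax(conc, 0))
}

#' Simulate N2 isotopologue time series
#'
#' Forward model of the isotope pairing assumptions. Denitrification
#' produces `D_a / 2` N2 pairs per hour, distributed binomially over the
#' isotopologues at the 15NO3- labelling fraction `epsilon`:
#' `(1-e)^2 : 2e(1-e) : e^2` to 28/29/30N2. Anammox pairs one
#' ammonium-derived and one nitrite-derived atom, so it contributes
#' `amx_a / 2` pairs split `(1-l)` to 28N2 and `l` to 29N2 and never
#' produces 30N2; the labelled-atom fraction `l` is `epsilon` under the
#' 15NO3- treatments and `f_a` under the 15NH4+ treatment (where
#' denitrification pairs only unlabelled atoms). Concentrations
#' accumulate linearly over the schedule on top of the ambient N2 pool
#' and get seeded Gaussian measurement noise.
#'
#' @param p An `iptflux_params` object.
#' @param vessel_ids Character vector of vessels to simulate (independent
#'   noise draws).
#' @param treatment `"no3"` (15NO3- addition) or `"nh4"` (15NH4+ +
#'   14NO3-).
#' @param seed RNG seed (default `p$seed`).
#' @return Long incubation tibble (28/29/30N2 in uM N2).
#' @export
simulate_n2_series <- function(p, vessel_ids = "M1",
                               treatment = c("no3", "nh4"),
                               seed = p$seed) {
  stopifnot(inherits(p, "iptflux_params"))
  treatment <- match.arg(treatment)
  eps <- if (treatment == "no3") p$epsilon else 0
  lab <- if (treatment == "no3") p$epsilon else p$f_a
  d_pairs <- p$D_a / 2
  a_pairs <- p$amx_a / 2
  s28 <- rate_to_slope(d_pairs * (1 - eps)^2 + a_pairs * (1 - lab), p$vessel)
  s29 <- rate_to_slope(d_pairs * 2 * eps * (1 - eps) + a_pairs * lab, p$vessel)
  s30 <- rate_to_slope(d_pairs * eps^2, p$vessel)
  x <- R_AIR / (1 + R_AIR)  # natural 15N atom fraction
  base <- p$baseline_n2_uM * c(`N2_28` = (1 - x)^2, `N2_29` = 2 * x * (1 - x),
                               `N2_30` = x^2)
  slopes <- c(N2_28 = s28, N2_29 = s29, N2_30 = s30)
  with_seed(seed, {
    purrr::map(vessel_ids, function(v) {
      purrr::map(names(slopes), function(a) {
        linear_series(p, v, a, base[[a]], slopes[[a]])
      }) |> list_rbind()
    }) |> list_rbind()
  })
}

#' Simulate the 15NH4+ production series of a DNRA incubation
#'
#' Under a 15NO3- treatment, DNRA reduces labelled nitrate to labelled
#' ammonium at rate `dnra_a * epsilon` (the labelled fraction of the
#' reduced pool), accumulating linearly over the ambient 15NH4+
#' background (natural abundance of a ~1 uM ammonium pool).
#'
#' @inheritParams simulate_n2_series
#' @param baseline_nh4_uM Ambient NH4+ pool used for the 15NH4+
#'   background (default 1 uM).
#' @return Long incubation tibble (analyte `NH4_15N`).
#' @export
simulate_15nh4_series <- function(p, vessel_ids = "M1",
                                  baseline_nh4_uM = 1, seed = p$seed) {
  stopifnot(inherits(p, "iptflux_params"))
  slope <- rate_to_slope(p$dnra_a * p$epsilon, p$vessel)
  base <- baseline_nh4_uM * R_AIR / (1 + R_AIR)
  with_seed(seed, {
    purrr::map(vessel_ids, function(v) {
      linear_series(p, v, "NH4_15N", base, slope)
    }) |> list_rbind()
  })
}

#' Simulate tissue 15N enrichment of a fixation incubation
#'
#' Unlabelled reference animals draw their tissue atom% from
#' `N(a_pn0_mean, a_pn0_sd^2)`. Labelled animals incorporate dissolved
#' 15N2 (source atom% `a_n2_source`) at the true rate `fix_a` for `dt_h`
#' hours, shifting their tissue atom% by
#' `fix_a * dt * sfdw / (pn * 1000) * (a_n2 - a_pn0)`, plus the same
#' measurement noise. Tissue N pools follow the animal's biomass at a
#' fixed N content.
#'
#' @inheritParams simulate_n2_series
#' @param n_labeled,n_unlabeled Number of incubated and reference
#'   animals.
#' @param dt_h Incubation length (default 12 h).
#' @param a_pn0_mean Natural-abundance tissue atom% (default 0.3663).
#' @param a_pn0_sd Between-animal + instrument SD of tissue atom%
#'   (default 0.0002, ~0.5 permil on homogenised ground tissue).
#' @param sfdw_mean_g,sfdw_sd_g Animal biomass distribution (defaults
#'   0.037 +/- 0.010 g SFDW).
#' @param n_content Tissue N content as mass fraction (default 0.10).
#' @return Tissue tibble (`animal_id`, `group`, `atom_pct`, `sfdw_g`,
#'   `pn_umol`, `dt_h`, `a_n2`) for [prepare_fixation_samples()].
#' @export
simulate_fixation_tissue <- function(p, n_labeled = 4, n_unlabeled = 10,
                                     dt_h = 12, a_pn0_mean = 0.3663,
                                     a_pn0_sd = 0.0002,
                                     sfdw_mean_g = 0.037, sfdw_sd_g = 0.010,
                                     n_content = 0.10, seed = p$seed) {
  stopifnot(inherits(p, "iptflux_params"), n_labeled >= 0, n_unlabeled >= 0)
  with_seed(seed, {
    sfdw <- pmax(rnorm(n_labeled, sfdw_mean_g, sfdw_sd_g), 0.005)
    pn <- sfdw * n_content * 1e6 / 14  # umol N in the soft tissue
    signal <- p$fix_a * dt_h * sfdw / (pn * 1000) * (p$a_n2_source - a_pn0_mean)
    labeled <- tibble(
      animal_id = paste0("ZM", seq_len(n_labeled)),
      group = "labeled",
      atom_pct = a_pn0_mean + signal +
        if (a_pn0_sd > 0) rnorm(n_labeled, 0, a_pn0_sd) else 0,
      sfdw_g = sfdw, pn_umol = pn, dt_h = dt_h, a_n2 = p$a_n2_source
    )
    unlabeled <- tibble(
      animal_id = paste0("REF", seq_len(n_unlabeled)),
      group = "unlabeled",
      atom_pct = a_pn0_mean +
        if (a_pn0_sd > 0) rnorm(n_unlabeled, 0, a_pn0_sd) else 0,
      sfdw_g = NA_real_, pn_umol = NA_real_, dt_h = NA_real_,
      a_n2 = NA_real_
    )
    bind_rows(labeled, unlabeled)
  })
}

#' Simulate paired bare / colonized core flux incubations
#'
#' Generates concentration time series for replicate sediment cores in
#' two conditions: bare sediment with baseline areal rates, and
#' mussel-colonized sediment with every rate multiplied by `effect`.
#' Feeds the full flux -> rank-test comparison workflow.
#'
#' @inheritParams simulate_n2_series
#' @param n_cores Replicate cores per condition.
#' @param effect Treatment multiplier applied to the colonized rates.
#' @param base_rates Named areal rates (umol m-2 h-1) of the bare
#'   sediment; negative = uptake.
#' @param baseline_conc Named ambient concentrations (uM).
#' @param core Core geometry (defaults: 8.4 cm i.d., 16 cm water
#'   column).
#' @param schedule Core sampling times (default 0, 2, 4 h, inside the
#'   <= 4 h incubation window).
#' @return List with `measurements` (long tibble), `geometry`, and
#'   `conditions` (vessel -> condition map).
#' @export
simulate_community_cores <- function(p, n_cores = 4, effect = 5,
                                     base_rates = c(O2 = -300, NH4 = -3,
                                                    NOx = -2, PO4 = -0.5),
                                     baseline_conc = c(O2 = 250, NH4 = 1,
                                                       NOx = 1.8, PO4 = 0.3),
                                     core = list(kind = "core",
                                                 water_volume_L = 0.887,
                                                 sediment_area_m2 = core_area(8.4),
                                                 biomass_g = 0),
                                     schedule = c(0, 2, 4),
                                     seed = p$seed) {
  stopifnot(inherits(p, "iptflux_params"), n_cores >= 0)
  if (n_cores == 0) {
    empty <- tibble(vessel_id = character(), analyte = character(),
                    time_h = numeric(), conc_uM = numeric())
    return(list(measurements = empty,
                geometry = tibble(vessel_id = character(), kind = character(),
                                  water_volume_L = numeric(),
                                  sediment_area_m2 = numeric(),
                                  biomass_g = numeric()),
                conditions = tibble(vessel_id = character(),
                                    condition = character())))
  }
  p_core <- p
  p_core$schedule <- schedule
  conditions <- tibble(
    vessel_id = c(paste0("S", seq_len(n_cores)),
                  paste0("SZM", seq_len(n_cores))),
    condition = rep(c("bare", "colonized"), each = n_cores)
  )
  geometry <- tibble(
    vessel_id = conditions$vessel_id, kind = "core",
    water_volume_L = core$water_volume_L,
    sediment_area_m2 = core$sediment_area_m2,
    biomass_g = ifelse(conditions$condition == "colonized", 0.134, 0)
  )
  measurements <- with_seed(seed, {
    purrr::pmap(conditions, function(vessel_id, condition) {
      mult <- if (condition == "colonized") effect else 1
      purrr::map(names(base_rates), function(a) {
        slope <- base_rates[[a]] * mult * core$sediment_area_m2 /
          core$water_volume_L
        linear_series(p_core, vessel_id, a, baseline_conc[[a]], slope)
      }) |> list_rbind()
    }) |> list_rbind()
  })
  list(measurements = measurements, geometry = geometry,
       conditions = conditions)
}
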