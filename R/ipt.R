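#' Production rates of single analytes on the vessel's normaliser basis
#'
#' Linear-regression slopes of concentration vs time converted to rates:
#' cores to umol m-2 h-1 (areal), microcosms to nmol g-1 h-1
#' (biomass-specific, control-corrected when a control series is given).
#' With `pooled = TRUE` all vessels' points are pooled into a single
#' regression per analyte (the whole-dataset significance test); the
#' returned row has `vessel_id = "pooled"`.
#'
#' @param data Long incubation tibble.
#' @param geometry Geometry tibble.
#' @param analytes Character vector of analytes to keep (default: all
#'   present).
#' @param control Optional water-only control series (microcosms).
#' @param pooled Pool replicate vessels into one regression per analyte.
#' @return Tibble with `vessel_id`, `analyte`, `rate`, `se`, `p_value`,
#'   `n_obs`, `basis` (`"areal_umol_m2_h"` or `"specific_nmol_g_h"`).
#' @export
production_rates <- function(data, geometry, analytes = NULL, control = NULL,
                             pooled = FALSE) {
  data <- validate_incubation(data)
  geometry <- validate_geometry(geometry)
  if (!is.null(analytes)) data <- filter(data, .data$analyte %in% analytes)
  if (nrow(data) == 0) abort("no measurements for the requested analytes",
                             class = "iptflux_validation_error")
  kind <- unique(geometry$kind[geometry$vessel_id %in% data$vessel_id])
  if (length(kind) != 1) abort("mixed or missing vessel kinds",
                               class = "iptflux_validation_error")
  basis <- if (kind == "core") "areal_umol_m2_h" else "specific_nmol_g_h"

  if (pooled) {
    # centre each vessel's series on its own intercept, then one regression
    pooled_data <- data |>
      group_by(.data$vessel_id, .data$analyte) |>
      mutate(conc_uM = .data$conc_uM - mean(.data$conc_uM)) |>
      ungroup() |>
      mutate(vessel_id = "pooled")
    sl <- pooled_data |>
      group_by(.data$vessel_id, .data$analyte) |>
      summarise(fit = list(fit_slope(.data$time_h, .data$conc_uM)),
                .groups = "drop") |>
      mutate(slope = map_dbl(.data$fit, "slope"),
             slope_se = map_dbl(.data$fit, "se"),
             p_value = map_dbl(.data$fit, "p_value"),
             n_obs = map_dbl(.data$fit, "n")) |>
      select(-"fit")
    # pooled rows use the mean scaling factor across vessels
    geom_scale <- mean(scale_factor(geometry, kind))
    ctrl <- control_slopes(control)
    sl |>
      left_join(ctrl, by = "analyte") |>
      mutate(control_slope = coalesce(.data$control_slope, 0),
             rate = (.data$slope - .data$control_slope) * geom_scale,
             se = .data$slope_se * geom_scale,
             basis = basis) |>
      select("vessel_id", "analyte", "rate", "se", "p_value", "n_obs", "basis")
  } else {
    ctrl <- control_slopes(control)
    slopes_by_vessel(data) |>
      left_join(ctrl, by = "analyte") |>
      mutate(control_slope = coalesce(.data$control_slope, 0)) |>
      inner_join(geometry, by = "vessel_id") |>
      mutate(rate = (.data$slope - .data$control_slope) *
               vessel_scale(.data$kind, .data$water_volume_L,
                            .data$sediment_area_m2, .data$biomass_g),
             se = .data$slope_se *
               vessel_scale(.data$kind, .data$water_volume_L,
                            .data$sediment_area_m2, .data$biomass_g),
             basis = basis) |>
      select("vessel_id", "analyte", "rate", "se", "p_value", "n_obs", "basis")
  }
}

vessel_scale <- function(kind, volume_L, area_m2, biomass_g) {
  ifelse(kind == "core", volume_L / area_m2, volume_L * 1000 / biomass_g)
}

scale_factor <- function(geometry, kind) {
  vessel_scale(geometry$kind, geometry$water_volume_L,
               geometry$sediment_area_m2, geometry$biomass_g)
}

control_slopes <- function(control) {
  if (is.null(control)) {
    return(tibble(analyte = character(), control_slope = numeric()))
  }
  validate_incubation(control) |>
    slopes_by_vessel() |>
    group_by(.data$analyte) |>
    summarise(control_slope = mean(.data$slope), .groups = "drop")
}

#' N2 isotopologue production rates
#'
#' Per-vessel regression slopes of 28N2 (when measured), 29N2 and 30N2,
#' converted to N2 production rates on the vessel's normaliser basis and
#' pivoted wide: one row per vessel with `p28`, `p29`, `p30` and their
#' standard errors and slope-test p-values. With `pooled = TRUE` a single
#' row carries the whole-dataset regression for significance gating.
#'
#' @inheritParams production_rates
#' @return Tibble of class `iptflux_isotopologue_rates`.
#' @export
isotopologue_slopes <- function(data, geometry, control = NULL, pooled = FALSE) {
  rates <- production_rates(
    data, geometry,
    analytes = c("N2_28", "N2_29", "N2_30"),
    control = control, pooled = pooled
  )
  if (!any(rates$analyte %in% c("N2_29", "N2_30"))) {
    abort("need 29N2 and 30N2 series", class = "iptflux_validation_error")
  }
  wide <- rates |>
    mutate(iso = sub("N2_", "p", .data$analyte)) |>
    select("vessel_id", "basis", "iso", "rate", "se", "p_value") |>
    tidyr::pivot_wider(names_from = "iso",
                       values_from = c("rate", "se", "p_value"),
                       names_glue = "{iso}_{.value}") |>
    rename_with(~ sub("_rate$", "", .x), ends_with("_rate"))
  for (col in c("p28", "p28_se", "p28_p_value",
                "p29", "p29_se", "p29_p_value",
                "p30", "p30_se", "p30_p_value")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  out <- select(wide, "vessel_id", "basis",
                "p28", "p28_se", "p28_p_value",
                "p29", "p29_se", "p29_p_value",
                "p30", "p30_se", "p30_p_value")
  class(out) <- c("iptflux_isotopologue_rates", class(out))
  out
}

#' Isotope-pairing partition of denitrification
#'
#' From the production rates of 29N2 and 30N2 after a 15NO3- addition,
#' computes the classical pairing estimates (N-atom units):
#' genuine denitrification of the labelled pool `D15 = p29 + 2 p30`,
#' of the unlabelled pool `D14 = D15 * p29 / (2 p30)`, their sum `D_tot`,
#' the water-nitrate-fuelled component `D_w = D15 / epsilon` (both
#' isotopes; `epsilon` is the 15N fraction of the water NO3- pool), and
#' the nitrification-coupled component `D_n = D_tot - D_w` (floored at 0
#' with a `DN_FLOORED` flag). Random pairing assumes a well-mixed NO3-
#' pool and no anammox; see [pairing_consistency()] for the diagnostic.
#'
#' A panel whose 29N2 and 30N2 slope p-values (or `gate_p`, e.g. the
#' pooled whole-dataset p) do not both fall below `alpha` is marked not
#' significant and its rates are reported as 0 with a `NOT_SIGNIFICANT`
#' flag; gating annotates the panel, the raw inputs stay in `rates`.
#' A `p30` at or below zero (or below `1e-12 * |p29|`) leaves `D14`
#' undefined (`UNDEFINED_D14` flag) rather than dividing by it.
#'
#' @param rates An `iptflux_isotopologue_rates` tibble (or any data frame
#'   with `p29`, `p30` and optional `p29_p_value`, `p30_p_value`).
#' @param epsilon 15N fraction of the water NO3- pool, in (0, 1].
#' @param alpha Significance gate (default 0.05).
#' @param gate_p Optional single p-value overriding the per-row slope
#'   p-values (pooled gating).
#' @return Tibble of class `iptflux_denit_panel` with columns `D15`,
#'   `D14`, `D_tot`, `D_w`, `D_n`, `Dn_Dw_ratio`, `significant`,
#'   `epsilon`, `flags`.
#' @export
ipt_partition <- function(rates, epsilon, alpha = 0.05, gate_p = NULL) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1)
  if (epsilon <= 0 || epsilon > 1) {
    abort("epsilon must lie in (0, 1]", class = "iptflux_validation_error")
  }
  rates <- as_tibble(rates)
  stopifnot(all(c("p29", "p30") %in% names(rates)))
  if (!"p29_p_value" %in% names(rates)) rates$p29_p_value <- NA_real_
  if (!"p30_p_value" %in% names(rates)) rates$p30_p_value <- NA_real_
  if (!"vessel_id" %in% names(rates)) rates$vessel_id <- paste0("V", seq_len(nrow(rates)))
  if (!"basis" %in% names(rates)) rates$basis <- NA_character_

  one <- function(p29, p30, p29p, p30p) {
    flags <- character()
    gp <- if (!is.null(gate_p)) gate_p else suppressWarnings(max(p29p, p30p))
    significant <- if (is.na(gp)) NA else gp < alpha
    p29c <- max(p29, 0)
    d14_defined <- is.finite(p30) && p30 > 0 && p30 > 1e-12 * abs(p29c)
    D15 <- p29c + 2 * max(p30, 0)
    if (d14_defined) {
      D14 <- D15 * p29c / (2 * p30)
      D_tot <- D14 + D15
      D_w <- D15 / epsilon
      D_n <- D_tot - D_w
      if (D_n < 0) {
        flags <- c(flags, "DN_FLOORED")
        D_n <- 0
      }
    } else {
      flags <- c(flags, "UNDEFINED_D14")
      D14 <- D_tot <- D_w <- D_n <- NA_real_
    }
    if (isFALSE(significant)) {
      flags <- c(flags, "NOT_SIGNIFICANT")
      D15 <- D14 <- D_tot <- D_w <- D_n <- 0
    }
    tibble(D15 = D15, D14 = D14, D_tot = D_tot, D_w = D_w, D_n = D_n,
           Dn_Dw_ratio = ifelse(is.finite(D_w) && D_w > 0, D_n / D_w, NA_real_),
           significant = significant,
           flags = join_flags(flags))
  }

  out <- bind_cols(
    select(rates, "vessel_id", "basis"),
    purrr::pmap(list(rates$p29, rates$p30, rates$p29_p_value,
                     rates$p30_p_value), one) |> list_rbind()
  )
  out$epsilon <- epsilon
  class(out) <- c("iptflux_denit_panel", class(out))
  out
}

#' Pairing-consistency diagnostic
#'
#' Under random isotope pairing the isotopologue productions satisfy
#' `p29^2 = 4 p28 p30`; the ratio `p29^2 / (4 p28 p30)` is 1 for pure
#' denitrification and is driven above 1 by anammox (which produces 29N2
#' without the matching 30N2). Requires measured 28N2 production.
#'
#' @param rates An `iptflux_isotopologue_rates` tibble with `p28`.
#' @return The input with a `pairing_ratio` column.
#' @export
pairing_consistency <- function(rates) {
  rates <- as_tibble(rates)
  stopifnot(all(c("p28", "p29", "p30") %in% names(rates)))
  mutate(rates, pairing_ratio = ifelse(
    is.finite(.data$p28) & .data$p28 > 0 & .data$p30 > 0,
    .data$p29^2 / (4 * .data$p28 * .data$p30), NA_real_
  ))
}

#' Tracer concentration-independence check
#'
#' The isotope pairing technique assumes rates are independent of the
#' amount of added 15NO3-. Comparing panels from a low and a high tracer
#' addition, the check passes when the relative difference of the mean
#' total denitrification, `|D_low - D_high| / mean(D_low, D_high)`, is at
#' most `tol`. DNRA rates are compared the same way when supplied.
#' Non-significant panels are excluded; if either side has none, the
#' check is skipped (flagged, `pass = NA`).
#'
#' @param panel_low,panel_high `iptflux_denit_panel` tibbles from the two
#'   tracer levels.
#' @param tol Relative tolerance (default 0.25).
#' @param dnra_low,dnra_high Optional numeric vectors of DNRA rates from
#'   the two treatments.
#' @return A tibble with one row per compared quantity: `mean_low`,
#'   `mean_high`, `ratio` (high/low), `rel_diff`, `pass`, `skipped`.
#' @export
independence_check <- function(panel_low, panel_high, tol = 0.25,
                               dnra_low = NULL, dnra_high = NULL) {
  stopifnot(tol > 0)
  compare <- function(lo, hi, what) {
    lo <- lo[is.finite(lo)]; hi <- hi[is.finite(hi)]
    if (length(lo) == 0 || length(hi) == 0) {
      return(tibble(quantity = what, mean_low = NA_real_, mean_high = NA_real_,
                    ratio = NA_real_, rel_diff = NA_real_, tol = tol,
                    pass = NA, skipped = TRUE))
    }
    m_lo <- mean(lo); m_hi <- mean(hi)
    rel <- abs(m_lo - m_hi) / mean(c(m_lo, m_hi))
    tibble(quantity = what, mean_low = m_lo, mean_high = m_hi,
           ratio = m_hi / m_lo, rel_diff = rel, tol = tol,
           pass = rel <= tol, skipped = FALSE)
  }
  keep <- function(panel) {
    panel$D_tot[is.na(panel$significant) | panel$significant]
  }
  out <- compare(keep(panel_low), keep(panel_high), "D_tot")
  if (!is.null(dnra_low) || !is.null(dnra_high)) {
    out <- bind_rows(out, compare(dnra_low %||% numeric(),
                                  dnra_high %||% numeric(), "DNRA"))
  }
  out
}

#' Anammox rate from the 15NH4+ + 14NO3- treatment
#'
#' Anammox pairs one ammonium-derived with one nitrite/nitrate-derived N
#' atom, so with 15NH4+ label (fraction `f_a` of the ammonium pool) it
#' produces 29N2 but never 30N2. The minimal estimator attributes all
#' 29N2 production in this treatment to anammox:
#' `AMX = p29 / f_a` N2 pairs per hour, i.e. `2 p29 / f_a` N atoms.
#' Detection requires a positive slope significant at `alpha`; when not
#' detected the rate is reported as 0 (the raw estimate stays in
#' `amx_raw`). Any 30N2 production in this treatment (would indicate
#' coupled processes) is carried through unreinterpreted in `p30`.
#'
#' @param rates `iptflux_isotopologue_rates` from the 15NH4+ treatment.
#' @param f_a 15N fraction of the ammonium pool, in (0, 1].
#' @param alpha Detection significance level (default 0.05).
#' @return Tibble with `amx_n2_pairs`, `amx_n_atoms`, `amx_raw`,
#'   `detected` per vessel.
#' @export
anammox_rate <- function(rates, f_a, alpha = 0.05) {
  stopifnot(is.numeric(f_a), length(f_a) == 1)
  if (f_a <= 0 || f_a > 1) {
    abort("f_a must lie in (0, 1]", class = "iptflux_validation_error")
  }
  rates <- as_tibble(rates)
  stopifnot("p29" %in% names(rates))
  if (!"p29_p_value" %in% names(rates)) rates$p29_p_value <- NA_real_
  rates |>
    mutate(
      amx_raw = 2 * .data$p29 / f_a,
      detected = is.finite(.data$p29_p_value) &
        .data$p29_p_value < alpha & .data$p29 > 0,
      amx_n2_pairs = ifelse(.data$detected, .data$p29 / f_a, 0),
      amx_n_atoms = 2 * .data$amx_n2_pairs
    ) |>
    select(any_of(c("vessel_id", "basis")), "p29", "p29_p_value",
           any_of("p30"), "amx_n2_pairs", "amx_n_atoms", "amx_raw", "detected")
}
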