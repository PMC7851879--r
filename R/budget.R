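BUDGET_PROCESSES <- c("NH4_efflux", "NOx_efflux", "DON_efflux", "D_w", "D_n",
                      "DNRA", "N2_fixation", "O2_uptake")

#' Upscale a biomass-specific rate to an areal rate
#'
#' @param rate_nmol_g_h Biomass-specific rate (nmol g_SFDW-1 h-1).
#' @param areal_biomass_g_m2 Areal biomass (g SFDW m-2).
#' @return Areal rate in umol m-2 h-1.
#' @export
#' @examples
#' areal_from_specific(31.2, 134) # 4.18 umol m-2 h-1
areal_from_specific <- function(rate_nmol_g_h, areal_biomass_g_m2) {
  stopifnot(all(areal_biomass_g_m2 >= 0, na.rm = TRUE))
  rate_nmol_g_h * areal_biomass_g_m2 / 1000
}

#' Contribution of a part to a whole, in percent
#'
#' @param part,whole Rates on the same basis.
#' @return `100 * part / whole`; `NA` with a warning when `whole` is 0.
#' @export
#' @examples
#' contribution_fraction(21.9, 58.4) # ~37%
contribution_fraction <- function(part, whole) {
  out <- ifelse(whole != 0, 100 * part / whole, NA_real_)
  if (any(whole == 0, na.rm = TRUE)) warn("whole is 0; fraction undefined")
  out
}

#' Overestimation of the net N2 flux when fixation is ignored
#'
#' A net N2 efflux measured without accounting for simultaneous N2
#' fixation underestimates gross denitrification; equivalently,
#' attributing the whole net flux to denitrification overestimates the
#' true net flux by `100 * fixation / (denitrification - fixation)`
#' percent.
#'
#' @param denit Gross denitrification rate.
#' @param fixation N2 fixation rate (same basis).
#' @return Percent overestimation; `NA` with a warning when
#'   `denit <= fixation` (net influx regime).
#' @export
#' @examples
#' net_n2_overestimate(58.4, 21.9) # 60%
net_n2_overestimate <- function(denit, fixation) {
  out <- ifelse(denit > fixation, 100 * fixation / (denit - fixation),
                NA_real_)
  if (any(denit <= fixation, na.rm = TRUE)) {
    warn("denitrification <= fixation: net influx regime, overestimate undefined")
  }
  out
}

#' Extrapolate per-animal rates over population density scenarios
#'
#' Converts a per-individual rate (given directly, or as a
#' biomass-specific rate times mean individual biomass) to areal rates
#' over a set of population densities, with a min/median/max summary.
#'
#' @param scenarios Data frame with a `density_ind_m2` column.
#' @param per_individual_nmol_h Per-individual rate (nmol ind-1 h-1);
#'   alternative to the biomass pair below.
#' @param specific_rate_nmol_g_h Biomass-specific rate (nmol g-1 h-1).
#' @param mean_sfdw_g Mean individual shell-free dry weight (g).
#' @return The scenarios tibble with `areal_umol_m2_h`, plus a `summary`
#'   attribute (min/median/max tibble).
#' @export
#' @examples
#' density_scale(data.frame(density_ind_m2 = c(40, 12600, 57000)),
#'               specific_rate_nmol_g_h = 7.8, mean_sfdw_g = 0.037)
density_scale <- function(scenarios, per_individual_nmol_h = NULL,
                          specific_rate_nmol_g_h = NULL, mean_sfdw_g = NULL) {
  scenarios <- as_tibble(scenarios)
  stopifnot("density_ind_m2" %in% names(scenarios))
  if (any(scenarios$density_ind_m2 < 0)) {
    abort("density must be >= 0", class = "iptflux_validation_error")
  }
  if (is.null(per_individual_nmol_h)) {
    if (is.null(specific_rate_nmol_g_h) || is.null(mean_sfdw_g)) {
      abort("give per_individual_nmol_h, or specific_rate_nmol_g_h with mean_sfdw_g",
            class = "iptflux_validation_error")
    }
    per_individual_nmol_h <- specific_rate_nmol_g_h * mean_sfdw_g
  }
  out <- mutate(scenarios,
                per_individual_nmol_h = per_individual_nmol_h,
                areal_umol_m2_h = per_individual_nmol_h *
                  .data$density_ind_m2 / 1000)
  attr(out, "summary") <- tibble(
    min = min(out$areal_umol_m2_h),
    median = median(out$areal_umol_m2_h),
    max = max(out$areal_umol_m2_h)
  )
  out
}

#' Assemble the nitrogen budget table
#'
#' Joins community-scale areal rates (bare and colonized sediment) with
#' holobiont rates upscaled to the biomass present in the community
#' incubations. For each process the table reports the bare and
#' colonized areal rates, the colonization increment
#' (colonized - bare), the upscaled holobiont contribution, and the
#' holobiont share of the increment in percent. A contribution larger
#' than the colonized areal rate is flagged `EXCEEDS` (diagnostic, not
#' an error). A per-condition benthic N balance residual is attached:
#' `N2_fixation - (D_w + D_n) - (NH4 + NOx + DON effluxes)`; DNRA is an
#' internal transformation and does not cross the sediment-water
#' boundary. Every number is carried from its input row, never
#' recomputed.
#'
#' @param benthic Data frame with `process` (see Details), `condition`
#'   (`"bare"`/`"colonized"`), `areal_rate_umol_m2_h`.
#' @param holobiont Optional data frame with `process` and
#'   `specific_rate_nmol_g_h` (upscaled via `areal_biomass_g_m2`) or a
#'   ready `areal_rate_umol_m2_h` column.
#' @param areal_biomass_g_m2 Biomass present in the community
#'   incubations (g SFDW m-2).
#' @return Tibble of class `iptflux_budget`: one row per process x
#'   condition with the columns above, plus a `residuals` attribute
#'   (per-condition tibble).
#' @details Recognised processes: `r paste(BUDGET_PROCESSES, collapse = ", ")`.
#' @export
assemble_budget <- function(benthic, holobiont = NULL,
                            areal_biomass_g_m2 = NULL) {
  benthic <- as_tibble(benthic)
  stopifnot(all(c("process", "condition", "areal_rate_umol_m2_h") %in%
                  names(benthic)))
  bad <- setdiff(unique(benthic$process), BUDGET_PROCESSES)
  if (length(bad) > 0) {
    abort(paste0("unknown process(es): ", paste(bad, collapse = ", ")),
          class = "iptflux_validation_error")
  }

  holo <- NULL
  if (!is.null(holobiont) && nrow(as_tibble(holobiont)) > 0) {
    holo <- as_tibble(holobiont)
    if (!"areal_rate_umol_m2_h" %in% names(holo)) {
      if (is.null(areal_biomass_g_m2)) {
        abort("areal_biomass_g_m2 needed to upscale specific holobiont rates",
              class = "iptflux_validation_error")
      }
      holo$areal_rate_umol_m2_h <-
        areal_from_specific(holo$specific_rate_nmol_g_h, areal_biomass_g_m2)
    }
    holo <- select(holo, "process",
                   holobiont_contribution = "areal_rate_umol_m2_h")
  }

  wide <- benthic |>
    select("process", "condition", "areal_rate_umol_m2_h") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "areal_rate_umol_m2_h")
  for (cond in c("bare", "colonized")) {
    if (!cond %in% names(wide)) wide[[cond]] <- NA_real_
  }
  out <- wide |>
    mutate(increment = .data$colonized - .data$bare)
  if (!is.null(holo)) {
    out <- left_join(out, holo, by = "process")
  } else {
    out$holobiont_contribution <- NA_real_
  }
  out <- out |>
    mutate(
      holobiont_share_pct = ifelse(
        is.finite(.data$holobiont_contribution) & is.finite(.data$increment) &
          .data$increment != 0,
        100 * .data$holobiont_contribution / .data$increment, NA_real_),
      flags = ifelse(
        is.finite(.data$holobiont_contribution) & is.finite(.data$colonized) &
          .data$holobiont_contribution > .data$colonized,
        "EXCEEDS", "")
    )

  residual_for <- function(rates) {
    get0r <- function(p) {
      v <- rates$rate[rates$process == p]
      if (length(v) == 0 || !is.finite(v[1])) 0 else v[1]
    }
    get0r("N2_fixation") - (get0r("D_w") + get0r("D_n")) -
      (get0r("NH4_efflux") + get0r("NOx_efflux") + get0r("DON_efflux"))
  }
  residuals <- benthic |>
    group_by(.data$condition) |>
    group_modify(function(df, key) {
      tibble(residual_umol_m2_h = residual_for(
        tibble(process = df$process, rate = df$areal_rate_umol_m2_h)))
    }) |>
    ungroup()
  attr(out, "residuals") <- residuals
  class(out) <- c("iptflux_budget", class(out))
  out
}

#' @export
tidy.iptflux_budget <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x),
                      cols = c("bare", "colonized", "increment",
                               "holobiont_contribution"),
                      names_to = "quantity",
                      values_to = "areal_rate_umol_m2_h")
}
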