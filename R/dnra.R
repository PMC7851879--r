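#' Total DNRA rate from 15NH4+ production
#'
#' Dissimilatory nitrate reduction to ammonium is measured as the
#' production of 15NH4+ during a 15NO3- incubation. Assuming DNRA and
#' denitrification draw on the same nitrate pool, the measured labelled
#' production is scaled to the whole pool by the ratio of total to
#' labelled denitrification:
#' `DNRA_tot = p15NH4 * D_tot / D15`.
#' The significance gate for the 15NH4+ production regression is
#' `alpha = 0.10`; a non-significant rate is reported as 0 with a
#' `NOT_SIGNIFICANT` flag (raw estimate kept in `dnra_raw`).
#'
#' @param p15nh4 Data frame of 15NH4+ production rates per vessel
#'   (columns `vessel_id`, `rate` and optionally `p_value`, `se`,
#'   `basis`), e.g. from
#'   `production_rates(data, geometry, analytes = "NH4_15N")`.
#' @param panel An `iptflux_denit_panel` (matched by `vessel_id` when
#'   both have several rows; a single-row panel is recycled).
#' @param alpha Significance gate (default 0.10).
#' @param gate_p Optional pooled p-value overriding per-row p-values.
#' @return Tibble of class `iptflux_dnra` with `dnra15`, `dnra_total`,
#'   `dnra_raw`, `significant`, `flags`.
#' @export
dnra_total <- function(p15nh4, panel, alpha = 0.10, gate_p = NULL) {
  p15nh4 <- as_tibble(p15nh4)
  stopifnot("rate" %in% names(p15nh4))
  if (!"p_value" %in% names(p15nh4)) p15nh4$p_value <- NA_real_
  if (!"vessel_id" %in% names(p15nh4)) {
    p15nh4$vessel_id <- paste0("V", seq_len(nrow(p15nh4)))
  }
  panel <- as_tibble(panel)
  if (nrow(panel) == 1) {
    panel <- panel[rep(1, nrow(p15nh4)), ]
    panel$vessel_id <- p15nh4$vessel_id
  }
  joined <- inner_join(p15nh4,
                       select(panel, "vessel_id", "D15", "D_tot"),
                       by = "vessel_id")
  if (nrow(joined) == 0) {
    abort("no vessels shared between p15nh4 and panel",
          class = "iptflux_validation_error")
  }
  if (any(!is.finite(joined$D15) | joined$D15 <= 0)) {
    abort("D15 must be > 0 to scale 15NH4+ production to the whole pool",
          class = "iptflux_validation_error")
  }
  out <- joined |>
    mutate(
      dnra15 = .data$rate,
      dnra_raw = .data$rate * .data$D_tot / .data$D15,
      significant = if (!is.null(gate_p)) gate_p < alpha else
        ifelse(is.na(.data$p_value), NA, .data$p_value < alpha),
      dnra_total = ifelse(!is.na(.data$significant) & !.data$significant,
                          0, .data$dnra_raw),
      flags = ifelse(!is.na(.data$significant) & !.data$significant,
                     "NOT_SIGNIFICANT", "")
    ) |>
    select(any_of(c("vessel_id", "basis")), "dnra15", "dnra_total",
           "dnra_raw", "significant", "flags")
  class(out) <- c("iptflux_dnra", class(out))
  out
}

#' DNRA to denitrification ratio
#'
#' Ratio of DNRA to total denitrification, aggregated across vessels
#' either as ratio-of-means (default: mean DNRA over mean D_tot, the
#' aggregation that matches budget upscaling) or as mean-of-ratios
#' (per-vessel pairing). Vessels with `D_tot = 0` are undefined for the
#' per-vessel ratio and are dropped from the mean-of-ratios with a
#' warning.
#'
#' @param dnra An `iptflux_dnra` tibble (or numeric vector of DNRA
#'   rates).
#' @param panel An `iptflux_denit_panel` (or numeric vector of D_tot).
#' @param method `"ratio_of_means"` or `"mean_of_ratios"`.
#' @return A single numeric ratio (NA when total denitrification is 0).
#' @export
dnra_to_denit <- function(dnra, panel,
                          method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  d <- if (is.numeric(dnra)) dnra else dnra$dnra_total
  den <- if (is.numeric(panel)) panel else panel$D_tot
  if (method == "ratio_of_means") {
    m <- mean(den, na.rm = TRUE)
    if (!is.finite(m) || m == 0) {
      warn("mean denitrification is 0; ratio undefined")
      return(NA_real_)
    }
    mean(d, na.rm = TRUE) / m
  } else {
    ok <- is.finite(d) & is.finite(den) & den > 0
    if (any(!ok)) warn("dropping vessels with zero/undefined denitrification")
    if (!any(ok)) return(NA_real_)
    mean(d[ok] / den[ok])
  }
}
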