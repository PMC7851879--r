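# Least-squares slope of concentration vs time with its SE and the
# two-sided t-test p-value for slope = 0. Two points give the finite
# difference with SE 0 and an undefined p. A residual-free fit (noiseless
# series) gets p = 0 for a nonzero slope and p = 1 for a flat one, so
# degenerate inputs never produce NaN.
fit_slope <- function(time_h, conc_uM) {
  n <- length(time_h)
  if (n < 2) abort("need >= 2 samples to estimate a rate",
                   class = "iptflux_validation_error")
  if (n == 2) {
    return(list(slope = diff(conc_uM) / diff(time_h), se = 0,
                p_value = NA_real_, n = 2L))
  }
  fit <- lm(conc_uM ~ time_h)
  # summary.lm warns on residual-free fits; the degenerate p is resolved below
  sg <- suppressWarnings(summary(fit))
  sm <- sg$coefficients
  slope <- sm["time_h", "Estimate"]
  se <- sm["time_h", "Std. Error"]
  p <- sm["time_h", "Pr(>|t|)"]
  # residual variance at floating-point roundoff: the t-test is meaningless,
  # resolve by limit (p = 0 for a real trend, p = 1 for a flat series)
  scale_y <- max(abs(conc_uM), 1e-12)
  if (!is.finite(p) || sg$sigma < 1e-10 * scale_y) {
    flat <- abs(slope) * diff(range(time_h)) < 1e-9 * scale_y
    if (flat) slope <- 0
    se <- 0
    p <- if (flat) 1 else 0
  }
  list(slope = slope, se = se, p_value = p, n = n)
}

endpoint_slope <- function(time_h, conc_uM) {
  o <- order(time_h)
  t2 <- time_h[o][c(1, length(time_h))]
  c2 <- conc_uM[o][c(1, length(conc_uM))]
  list(slope = diff(c2) / diff(t2), se = 0, p_value = NA_real_,
       n = length(time_h))
}

# Lack-of-linearity check: significant quadratic curvature at alpha = 0.05
# (needs >= 4 points; fewer points cannot distinguish curvature from noise).
is_nonlinear <- function(time_h, conc_uM, alpha = 0.05) {
  if (length(time_h) < 4) return(FALSE)
  fit <- lm(conc_uM ~ time_h + I(time_h^2))
  sm <- suppressWarnings(summary(fit))$coefficients
  if (!"I(time_h^2)" %in% rownames(sm)) return(FALSE)
  p <- sm["I(time_h^2)", "Pr(>|t|)"]
  is.finite(p) && p < alpha
}

slopes_by_vessel <- function(data, method = "regression") {
  estimator <- if (method == "endpoints") endpoint_slope else fit_slope
  data |>
    group_by(.data$vessel_id, .data$analyte) |>
    summarise(
      fit = list(estimator(.data$time_h, .data$conc_uM)),
      nonlinear = is_nonlinear(.data$time_h, .data$conc_uM),
      drawdown = (first(.data$conc_uM, order_by = .data$time_h) -
                    last(.data$conc_uM, order_by = .data$time_h)) /
        ifelse(first(.data$conc_uM, order_by = .data$time_h) > 0,
               first(.data$conc_uM, order_by = .data$time_h), NA_real_),
      .groups = "drop"
    ) |>
    mutate(
      slope = map_dbl(.data$fit, "slope"),
      slope_se = map_dbl(.data$fit, "se"),
      p_value = map_dbl(.data$fit, "p_value"),
      n_obs = map_dbl(.data$fit, "n")
    ) |>
    select(-"fit")
}

#' Net sediment-water fluxes from core incubations
#'
#' The flux of each analyte is the least-squares slope of its
#' concentration time series multiplied by the enclosed water volume and
#' divided by the sediment area, giving umol m-2 h-1. Positive values are
#' effluxes (release to the water), negative values uptake. With only two
#' samples the slope is the finite difference. Oxygen series whose
#' concentration falls by more than `o2_drawdown_limit` of the initial
#' value are flagged `O2_DRAWDOWN_EXCEEDED` (the incubation-length rule
#' that keeps concentration changes linear); series with significant
#' curvature are flagged `NONLINEAR`. Flags annotate, they never suppress
#' a flux.
#'
#' @param data Long incubation tibble (`vessel_id`, `analyte`, `time_h`,
#'   `conc_uM`).
#' @param geometry Geometry tibble (see [read_geometry()]); all vessels
#'   must be cores.
#' @param method `"regression"` (default) or `"endpoints"`.
#' @param o2_drawdown_limit Fractional O2 decrease that triggers the QC
#'   flag (default 0.20).
#' @return A tibble with one row per vessel x analyte: `flux_umol_m2_h`,
#'   `se`, `p_value`, `n_obs`, `qc_flags`.
#' @export
net_flux_core <- function(data, geometry, method = c("regression", "endpoints"),
                          o2_drawdown_limit = 0.20) {
  method <- match.arg(method)
  data <- validate_incubation(data)
  geometry <- validate_geometry(geometry)
  if (!all(geometry$kind == "core")) {
    abort("net_flux_core() requires core geometry",
          class = "iptflux_validation_error")
  }
  slopes_by_vessel(data, method) |>
    inner_join(geometry, by = "vessel_id") |>
    mutate(
      flux_umol_m2_h = .data$slope * .data$water_volume_L / .data$sediment_area_m2,
      se = .data$slope_se * .data$water_volume_L / .data$sediment_area_m2,
      qc_flags = mapply(
        join_flags,
        ifelse(.data$analyte == "O2" & !is.na(.data$drawdown) &
                 .data$drawdown > o2_drawdown_limit,
               "O2_DRAWDOWN_EXCEEDED", ""),
        ifelse(.data$nonlinear, "NONLINEAR", "")
      )
    ) |>
    select("vessel_id", "analyte", "flux_umol_m2_h", "se", "p_value",
           "n_obs", "qc_flags")
}

#' Biomass-specific net rates from holobiont microcosm incubations
#'
#' The production slope of each analyte, minus the slope of the same
#' analyte in the water-only control (when `control_correct`), is scaled
#' by the microcosm water volume and normalised per gram of shell-free
#' dry weight, giving nmol g-1 h-1. The single shared control contributes
#' no SE (documented limitation of the one-control design). Negative
#' corrected rates are returned as-is.
#'
#' @param data Long incubation tibble for the mussel microcosms.
#' @param geometry Geometry tibble; all vessels must be microcosms with
#'   `biomass_g > 0`.
#' @param control Long incubation tibble for the water-only control
#'   vessel, or `NULL` for no correction.
#' @param control_correct Subtract the control slope (default `TRUE`).
#' @param method `"regression"` or `"endpoints"`.
#' @return A tibble with `rate_nmol_g_h`, `se`, `p_value`, `n_obs`,
#'   `qc_flags` per vessel x analyte.
#' @export
net_flux_microcosm <- function(data, geometry, control = NULL,
                               control_correct = TRUE,
                               method = c("regression", "endpoints")) {
  method <- match.arg(method)
  data <- validate_incubation(data)
  geometry <- validate_geometry(geometry)
  if (!all(geometry$kind == "microcosm")) {
    abort("net_flux_microcosm() requires microcosm geometry",
          class = "iptflux_validation_error")
  }
  if (any(geometry$biomass_g <= 0)) {
    abort("microcosm vessels need biomass_g > 0",
          class = "iptflux_validation_error")
  }
  ctrl_slopes <- if (!is.null(control) && control_correct) {
    validate_incubation(control) |>
      slopes_by_vessel(method) |>
      group_by(.data$analyte) |>
      summarise(control_slope = mean(.data$slope), .groups = "drop")
  } else {
    tibble(analyte = character(), control_slope = numeric())
  }
  corrected <- any(nrow(ctrl_slopes) > 0)
  slopes_by_vessel(data, method) |>
    left_join(ctrl_slopes, by = "analyte") |>
    mutate(control_slope = coalesce(.data$control_slope, 0)) |>
    inner_join(geometry, by = "vessel_id") |>
    mutate(
      rate_nmol_g_h = (.data$slope - .data$control_slope) *
        .data$water_volume_L * 1000 / .data$biomass_g,
      se = .data$slope_se * .data$water_volume_L * 1000 / .data$biomass_g,
      qc_flags = mapply(
        join_flags,
        ifelse(corrected & .data$analyte %in% ctrl_slopes$analyte,
               "CONTROL_CORRECTED", ""),
        ifelse(.data$nonlinear, "NONLINEAR", "")
      )
    ) |>
    select("vessel_id", "analyte", "rate_nmol_g_h", "se", "p_value",
           "n_obs", "qc_flags")
}

#' Correct a time series for subsampling withdrawals
#'
#' When an aliquot is withdrawn and replaced with water of known
#' concentration, every later reading is diluted. This reconstructs the
#' production-only series by adding back, at each withdrawal, the
#' concentration jump `f * (C_before - C_replacement)` (f = withdrawn
#' fraction of the vessel volume) to all subsequent readings. The
#' measurement at the withdrawal time is taken before the exchange.
#' Sequential withdrawals compose exactly.
#'
#' @param data Long incubation tibble.
#' @param geometry Geometry tibble supplying vessel volumes.
#' @param withdrawals Tibble with `vessel_id`, `time_h`,
#'   `volume_removed_L`, `replacement_conc_uM`, and optionally `analyte`
#'   (absent = applies to every analyte of that vessel).
#' @return The corrected incubation tibble.
#' @export
dilution_correct <- function(data, geometry, withdrawals) {
  data <- validate_incubation(data)
  geometry <- validate_geometry(geometry)
  stopifnot(all(c("vessel_id", "time_h", "volume_removed_L",
                  "replacement_conc_uM") %in% names(withdrawals)))
  withdrawals <- as_tibble(withdrawals)
  if (!"analyte" %in% names(withdrawals)) withdrawals$analyte <- NA_character_

  correct_one <- function(df) {
    vid <- df$vessel_id[[1]]
    an <- df$analyte[[1]]
    vol <- geometry$water_volume_L[match(vid, geometry$vessel_id)]
    w <- withdrawals |>
      filter(.data$vessel_id == vid,
             is.na(.data$analyte) | .data$analyte == an) |>
      arrange(.data$time_h)
    if (nrow(w) == 0) return(df)
    if (any(w$volume_removed_L >= vol)) {
      abort("withdrawal volume must be smaller than the vessel volume",
            class = "iptflux_validation_error")
    }
    if (!all(w$time_h %in% df$time_h)) {
      abort(sprintf("withdrawal at a time not sampled in vessel %s", vid),
            class = "iptflux_validation_error")
    }
    df <- arrange(df, .data$time_h)
    offset <- 0
    out <- df$conc_uM
    for (i in seq_along(df$time_h)) {
      out[i] <- df$conc_uM[i] + offset
      j <- which(w$time_h == df$time_h[i])
      for (k in j) {
        f <- w$volume_removed_L[k] / vol
        offset <- offset + f * (df$conc_uM[i] - w$replacement_conc_uM[k])
      }
    }
    df$conc_uM <- out
    df
  }

  data |>
    group_by(.data$vessel_id, .data$analyte) |>
    group_split() |>
    map(correct_one) |>
    list_rbind() |>
    arrange(.data$vessel_id, .data$analyte, .data$time_h)
}
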