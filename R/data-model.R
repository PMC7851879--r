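#' Read a long-format incubation measurement table
#'
#' Expects an RFC-4180 CSV with one row per (vessel, time, analyte)
#' observation and columns `vessel_id`, `analyte`, `time_h`, `conc_uM`.
#' Lines starting with `#` are treated as metadata comments; if a
#' `# units:` line is present it must declare `time_h=h` and `conc_uM=uM`
#' (units are fixed, never inferred). Validates the measurement
#' invariants: known analytes, strictly increasing times within each
#' vessel/analyte series, and non-negative concentrations.
#'
#' @param path CSV file path.
#' @param blank Optional named numeric vector of per-analyte blank
#'   concentrations (uM) subtracted from the matching analyte; default no
#'   correction. Blank-corrected values are floored at 0.
#' @return A tibble with columns `vessel_id`, `analyte`, `time_h`,
#'   `conc_uM`.
#' @export
read_incubation <- function(path, blank = NULL) {
  check_units_header(path)
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  validate_incubation(raw, blank = blank)
}

check_units_header <- function(path) {
  top <- readLines(path, n = 10L, warn = FALSE)
  units_line <- grep("^#\\s*units:", top, value = TRUE)
  if (length(units_line) > 0) {
    decl <- units_line[[1]]
    if (!grepl("time_h\\s*=\\s*h", decl) || !grepl("conc_uM\\s*=\\s*uM", decl)) {
      abort(sprintf(
        "unit declaration %s does not match the fixed units (time_h=h, conc_uM=uM)",
        trimws(sub("^#", "", decl))
      ), class = "iptflux_schema_error")
    }
  }
  invisible(path)
}

#' Validate (and optionally blank-correct) an incubation table
#'
#' @param data A data frame with columns `vessel_id`, `analyte`, `time_h`,
#'   `conc_uM`.
#' @inheritParams read_incubation
#' @return The validated tibble.
#' @export
validate_incubation <- function(data, blank = NULL) {
  required <- c("vessel_id", "analyte", "time_h", "conc_uM")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
          class = "iptflux_schema_error")
  }
  data <- as_tibble(data)
  unknown <- setdiff(unique(data$analyte), ANALYTES)
  if (length(unknown) > 0) {
    abort(paste0("unknown analyte(s): ", paste(unknown, collapse = ", ")),
          class = "iptflux_schema_error")
  }
  if (!is.null(blank)) {
    stopifnot(is.numeric(blank), !is.null(names(blank)))
    idx <- data$analyte %in% names(blank)
    data$conc_uM[idx] <- pmax(data$conc_uM[idx] - blank[data$analyte[idx]], 0)
  }
  if (any(!is.finite(data$time_h)) || any(data$time_h < 0)) {
    abort("times must be finite and >= 0 h", class = "iptflux_validation_error")
  }
  if (any(!is.finite(data$conc_uM)) || any(data$conc_uM < 0)) {
    abort("concentrations must be finite and >= 0 uM",
          class = "iptflux_validation_error")
  }
  bad <- data |>
    group_by(.data$vessel_id, .data$analyte) |>
    summarise(ok = all(diff(.data$time_h[order(.data$time_h)]) > 0) &&
                !anyDuplicated(.data$time_h),
              .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-monotonic or duplicated times in vessel(s): %s",
      paste(unique(bad$vessel_id), collapse = ", ")
    ), class = "iptflux_validation_error")
  }
  arrange(data, .data$vessel_id, .data$analyte, .data$time_h)
}

#' Read a vessel geometry table
#'
#' CSV with columns `vessel_id`, `kind` (`"core"` or `"microcosm"`),
#' `water_volume_L`, `sediment_area_m2` (cores only; empty for
#' microcosms), `biomass_g` (shell-free dry weight; 0 for bare sediment
#' or water-only controls).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_geometry <- function(path) {
  validate_geometry(readr::read_csv(path, comment = "#", show_col_types = FALSE))
}

#' @rdname read_geometry
#' @param data A data frame with the geometry columns.
#' @export
validate_geometry <- function(data) {
  required <- c("vessel_id", "kind", "water_volume_L", "biomass_g")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
          class = "iptflux_schema_error")
  }
  data <- as_tibble(data)
  if (!"sediment_area_m2" %in% names(data)) data$sediment_area_m2 <- NA_real_
  if (!all(data$kind %in% c("core", "microcosm"))) {
    abort("kind must be 'core' or 'microcosm'", class = "iptflux_schema_error")
  }
  if (any(data$water_volume_L <= 0)) {
    abort("water_volume_L must be > 0", class = "iptflux_validation_error")
  }
  core <- data$kind == "core"
  if (any(core & (is.na(data$sediment_area_m2) | data$sediment_area_m2 <= 0))) {
    abort("cores must have sediment_area_m2 > 0",
          class = "iptflux_validation_error")
  }
  if (any(data$biomass_g < 0)) {
    abort("biomass_g must be >= 0", class = "iptflux_validation_error")
  }
  data
}

#' Sediment area of a cylindrical core liner
#'
#' @param inner_diameter_cm Inner diameter in cm (the study's liners:
#'   8.4 cm).
#' @return Area in m2.
#' @export
#' @examples
#' core_area(8.4) # 0.005542 m2
core_area <- function(inner_diameter_cm) {
  pi * (inner_diameter_cm / 200)^2
}

#' Read a tracer specification
#'
#' YAML (or CSV) describing what label was added to each treatment:
#' `treatment`, `label` (one of `NO3_15N`, `NH4_15N`, `N2_30`),
#' `added_uM`, and `epsilon`, the 15N mole fraction of the labelled
#' dissolved pool after addition (epsilon for nitrate, f_a for ammonium,
#' source atom fraction for dissolved N2).
#'
#' @param path File path (`.yaml`/`.yml` or `.csv`).
#' @return A validated tibble with one row per treatment.
#' @export
read_tracer <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    spec <- yaml::read_yaml(path)
    data <- purrr::map(spec, as_tibble) |> list_rbind()
  } else {
    data <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  }
  validate_tracer(data)
}

#' @rdname read_tracer
#' @param data A data frame with the tracer columns.
#' @export
validate_tracer <- function(data) {
  required <- c("treatment", "label", "added_uM", "epsilon")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
          class = "iptflux_schema_error")
  }
  data <- as_tibble(data)
  if (!all(data$label %in% c("NO3_15N", "NH4_15N", "N2_30"))) {
    abort("label must be one of NO3_15N, NH4_15N, N2_30",
          class = "iptflux_schema_error")
  }
  if (any(data$epsilon < 0 | data$epsilon > 1)) {
    abort("epsilon must lie in [0, 1]", class = "iptflux_validation_error")
  }
  if (any(data$added_uM < 0)) {
    abort("added_uM must be >= 0", class = "iptflux_validation_error")
  }
  data
}

#' Write an incubation table (round-trip safe)
#'
#' @param data A validated incubation tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_incubation <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Convert a wide measurement table to the long layout
#'
#' Convenience for instrument exports with one column per analyte.
#'
#' @param data Data frame with `vessel_id`, `time_h` and one column per
#'   analyte.
#' @return Long tibble with `vessel_id`, `analyte`, `time_h`, `conc_uM`.
#' @export
wide_to_long <- function(data) {
  out <- tidyr::pivot_longer(
    as_tibble(data),
    cols = -c("vessel_id", "time_h"),
    names_to = "analyte", values_to = "conc_uM"
  )
  validate_incubation(tidyr::drop_na(out, "conc_uM"))
}

#' Derive nitrate, DIN and DON from measured nitrogen pools
#'
#' Nitrate is the difference between NOx and nitrite; DIN is ammonium
#' plus NOx; DON is the difference between total dissolved N and DIN.
#' Because both differences are noise-sensitive near zero, negative
#' derived values are clipped to 0 and flagged (in `derive_flags`)
#' rather than raised as errors.
#'
#' @param data Data frame with numeric columns `NH4`, `NO2`, `NOx` and
#'   optionally `TDN` (all uM).
#' @return The input with added columns `NO3`, `DIN`, `DON` (if `TDN`
#'   present) and `derive_flags`.
#' @export
#' @examples
#' derive_concentrations(data.frame(NH4 = 2, NO2 = 1, NOx = 5, TDN = 60))
derive_concentrations <- function(data) {
  stopifnot(all(c("NH4", "NO2", "NOx") %in% names(data)))
  data <- as_tibble(data)
  no3 <- data$NOx - data$NO2
  flag_no3 <- ifelse(no3 < 0, "NEGATIVE_NO3_CLIPPED", "")
  data$NO3 <- pmax(no3, 0)
  data$DIN <- data$NH4 + data$NOx
  flag_don <- ""
  if ("TDN" %in% names(data)) {
    don <- data$TDN - data$DIN
    flag_don <- ifelse(don < 0, "NEGATIVE_DON_CLIPPED", "")
    data$DON <- pmax(don, 0)
  }
  data$derive_flags <- mapply(join_flags, flag_no3, flag_don, USE.NAMES = FALSE)
  data
}
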