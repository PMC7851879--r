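#' Run the full inference pipeline
#'
#' Orchestrates the stages end-to-end on one dataset: community core
#' fluxes, holobiont isotopologue rates and their IPT partition at the
#' low and high tracer level, the tracer-independence check, anammox
#' from the 15NH4+ treatment, DNRA, N2 fixation, the bare-vs-colonized
#' rank tests, and the areal budget. With `input = NULL` the simulator
#' generates the dataset first (written alongside the outputs, so a run
#' is fully self-contained); otherwise `input` names a directory with
#' `community.csv`, `community_geometry.csv`, `holobiont_low.csv`,
#' `holobiont_high.csv`, `holobiont_nh4.csv`, `holobiont_geometry.csv`,
#' `tissue.csv` and `tracer.csv` in the package's CSV schemas.
#'
#' Stages run in dependency order; a failing stage leaves earlier
#' outputs in place and is recorded in the manifest (`failed_stage`).
#' The manifest (JSON) lists the configuration snapshot, seed, input
#' digests, output files and warnings.
#'
#' @param out_dir Output directory (created if needed).
#' @param params An `iptflux_params` ground truth (simulated runs).
#' @param config An `iptflux_config`.
#' @param input Optional input directory of CSVs; `NULL` simulates.
#' @param areal_biomass_g_m2 Biomass for holobiont upscaling (default
#'   134 g SFDW m-2).
#' @return The run manifest (list), invisibly. Outputs and
#'   `manifest.json` are written to `out_dir`.
#' @export
run_pipeline <- function(out_dir, params = true_parameters(),
                         config = run_config(), input = NULL,
                         areal_biomass_g_m2 = 134) {
  stopifnot(inherits(config, "iptflux_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("iptflux")),
    seed = config$rng_seed,
    config = unclass(config),
    inputs = list(), outputs = character(), warnings = character(),
    failed_stage = NULL
  )
  out_path <- function(name) file.path(out_dir, name)
  save_csv <- function(df, name) {
    readr::write_csv(df, out_path(name))
    manifest$outputs <<- c(manifest$outputs, name)
  }

  # --- inputs: simulate or read ------------------------------------------
  seed <- config$rng_seed
  if (is.null(input)) {
    p_low <- params
    p_high <- params
    p_high$epsilon <- min(0.9, params$epsilon * 1.3)
    community <- simulate_community_cores(params, seed = seed)
    low_n2 <- simulate_n2_series(p_low, paste0("L", 1:4), "no3", seed = seed + 1)
    high_n2 <- simulate_n2_series(p_high, paste0("H", 1:4), "no3", seed = seed + 2)
    nh4_n2 <- simulate_n2_series(params, paste0("A", 1:4), "nh4", seed = seed + 3)
    low_dnra <- simulate_15nh4_series(p_low, paste0("L", 1:4), seed = seed + 4)
    tissue <- simulate_fixation_tissue(params, seed = seed + 5)
    holo_geom <- tibble(
      vessel_id = c(paste0("L", 1:4), paste0("H", 1:4), paste0("A", 1:4)),
      kind = "microcosm",
      water_volume_L = params$vessel$water_volume_L,
      sediment_area_m2 = NA_real_,
      biomass_g = params$vessel$biomass_g
    )
    tracer <- tibble(
      treatment = c("low", "high", "nh4"),
      label = c("NO3_15N", "NO3_15N", "NH4_15N"),
      added_uM = c(6.2, 19.1, 6.3),
      epsilon = c(p_low$epsilon, p_high$epsilon, params$f_a)
    )
    save_csv(community$measurements, "community.csv")
    save_csv(community$geometry, "community_geometry.csv")
    save_csv(community$conditions, "community_conditions.csv")
    save_csv(bind_rows(low_n2, low_dnra), "holobiont_low.csv")
    save_csv(high_n2, "holobiont_high.csv")
    save_csv(nh4_n2, "holobiont_nh4.csv")
    save_csv(holo_geom, "holobiont_geometry.csv")
    save_csv(tissue, "tissue.csv")
    save_csv(tracer, "tracer.csv")
    conditions <- community$conditions
    community <- community$measurements
    comm_geom <- read_geometry(out_path("community_geometry.csv"))
  } else {
    need <- c("community.csv", "community_geometry.csv",
              "community_conditions.csv", "holobiont_low.csv",
              "holobiont_high.csv", "holobiont_nh4.csv",
              "holobiont_geometry.csv", "tissue.csv", "tracer.csv")
    paths <- file.path(input, need)
    missing <- need[!file.exists(paths)]
    if (length(missing) > 0) {
      abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")),
            class = "iptflux_schema_error")
    }
    manifest$inputs <- as.list(tools::md5sum(paths))
    community <- read_incubation(file.path(input, "community.csv"))
    comm_geom <- read_geometry(file.path(input, "community_geometry.csv"))
    conditions <- readr::read_csv(file.path(input, "community_conditions.csv"),
                                  show_col_types = FALSE)
    low_n2 <- read_incubation(file.path(input, "holobiont_low.csv"))
    low_dnra <- filter(low_n2, .data$analyte == "NH4_15N")
    low_n2 <- filter(low_n2, .data$analyte != "NH4_15N")
    high_n2 <- read_incubation(file.path(input, "holobiont_high.csv"))
    nh4_n2 <- read_incubation(file.path(input, "holobiont_nh4.csv"))
    holo_geom <- read_geometry(file.path(input, "holobiont_geometry.csv"))
    tissue <- readr::read_csv(file.path(input, "tissue.csv"),
                              show_col_types = FALSE)
    tracer <- read_tracer(file.path(input, "tracer.csv"))
  }
  eps_low <- tracer$epsilon[tracer$treatment == "low"]
  eps_high <- tracer$epsilon[tracer$treatment == "high"]
  f_a <- tracer$epsilon[tracer$treatment == "nh4"]

  run_stage <- function(stage, code) {
    if (!is.null(manifest$failed_stage)) return(NULL)
    tryCatch(
      withCallingHandlers(code, warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        manifest$failed_stage <<- stage
        manifest$warnings <<- c(manifest$warnings,
                                paste0(stage, " failed: ", conditionMessage(e)))
        NULL
      }
    )
  }

  # --- stage: community fluxes -------------------------------------------
  fluxes <- run_stage("fluxes", {
    fx <- net_flux_core(community, comm_geom, method = config$flux_method,
                        o2_drawdown_limit = config$o2_drawdown_limit) |>
      left_join(conditions, by = "vessel_id")
    save_csv(fx, "fluxes.csv")
    fx
  })

  # --- stage: IPT panels -------------------------------------------------
  panels <- run_stage("ipt", {
    panel_of <- function(n2, eps) {
      rates <- isotopologue_slopes(n2, holo_geom)
      pooled <- isotopologue_slopes(n2, holo_geom, pooled = TRUE)
      gate <- max(pooled$p29_p_value, pooled$p30_p_value)
      ipt_partition(rates, eps, alpha = config$significance_alpha_denit,
                    gate_p = gate)
    }
    p_lo <- panel_of(low_n2, eps_low)
    p_hi <- panel_of(high_n2, eps_high)
    save_csv(mutate(p_lo, treatment = "low"), "panel_low.csv")
    save_csv(mutate(p_hi, treatment = "high"), "panel_high.csv")
    list(low = p_lo, high = p_hi)
  })

  indep <- run_stage("independence", {
    ic <- independence_check(panels$low, panels$high,
                             tol = config$independence_tolerance)
    save_csv(ic, "independence.csv")
    ic
  })

  amx <- run_stage("anammox", {
    a <- anammox_rate(isotopologue_slopes(nh4_n2, holo_geom), f_a,
                      alpha = config$significance_alpha_denit)
    save_csv(a, "anammox.csv")
    a
  })

  dnra <- run_stage("dnra", {
    p15 <- production_rates(low_dnra, holo_geom, analytes = "NH4_15N")
    d <- dnra_total(p15, panels$low, alpha = config$significance_alpha_dnra)
    save_csv(d, "dnra.csv")
    d
  })

  fixation <- run_stage("fixation", {
    fx <- prepare_fixation_samples(tissue) |>
      fixation_rate() |>
      detect_incorporation(k = config$fixation_sd_multiplier)
    save_csv(fx, "fixation.csv")
    fx
  })

  # --- stage: treatment comparisons --------------------------------------
  stats_out <- run_stage("stats", {
    by_cond <- function(analyte) {
      f <- filter(fluxes, .data$analyte == !!analyte)
      mann_whitney_exact(f$flux_umol_m2_h[f$condition == "bare"],
                         f$flux_umol_m2_h[f$condition == "colonized"])
    }
    tests <- purrr::map(unique(fluxes$analyte), function(a) {
      mutate(tidy(by_cond(a)), analyte = a)
    }) |> list_rbind()
    save_csv(tests, "rank_tests.csv")
    tests
  })

  # --- stage: budget ------------------------------------------------------
  budget <- run_stage("budget", {
    mean_flux <- fluxes |>
      filter(.data$analyte %in% c("NH4", "NOx")) |>
      group_by(.data$condition, .data$analyte) |>
      summarise(rate = mean(.data$flux_umol_m2_h), .groups = "drop") |>
      mutate(process = paste0(.data$analyte, "_efflux"))
    benthic <- tibble(
      process = mean_flux$process, condition = mean_flux$condition,
      areal_rate_umol_m2_h = mean_flux$rate
    )
    holo <- tibble(
      process = c("D_w", "DNRA", "N2_fixation"),
      specific_rate_nmol_g_h = c(
        mean(panels$low$D_tot, na.rm = TRUE),
        mean(dnra$dnra_total, na.rm = TRUE),
        mean(fixation$rate_nmol_g_h, na.rm = TRUE)
      )
    )
    b <- assemble_budget(benthic, holo,
                         areal_biomass_g_m2 = areal_biomass_g_m2)
    save_csv(as_tibble(b), "budget.csv")
    b
  })

  manifest$outputs <- unique(manifest$outputs)
  manifest$output_digests <-
    as.list(tools::md5sum(file.path(out_dir, manifest$outputs)))
  names(manifest$output_digests) <- manifest$outputs
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
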