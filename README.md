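# iptflux

Rate inference for ¹⁵N stable-isotope tracer incubations in aquatic
nitrogen-cycle studies: benthic core fluxes, isotope-pairing
denitrification, DNRA, anammox, ¹⁵N₂ fixation, and biomass-to-areal
nitrogen budgets. The package was built around experiments on
filter-feeder *holobionts* (an animal plus its microbiome, incubated as
one unit — e.g. a single zebra mussel in a sealed microcosm), but every
stage works on any incubation time series in the same tabular layout.

It is aimed at benthic biogeochemists who have concentration time
series from sealed cores or microcosms and want the full chain —
quality-controlled net fluxes, isotope-pairing partitioning with its
assumption checks, significance gating, exact small-sample treatment
comparisons, and upscaled areal budgets — in one pipe-friendly
toolbox, with a forward simulator that makes every estimator testable
against known ground truth.

## The calculus

**Net fluxes.** For a sealed core, the flux of an analyte is the
least-squares slope of its concentration over time scaled by enclosed
water volume and sediment area, `F = b·V/A` (µmol m⁻² h⁻¹, positive =
efflux). Microcosm rates are control-corrected and biomass-normalised:
`R = (b − b_ctrl)·V/W` (nmol g_SFDW⁻¹ h⁻¹). Oxygen drawdown beyond 20%
of the initial concentration flags the incubation (linearity guard);
flags annotate, they never drop data.

**Isotope pairing (IPT).** After ¹⁵NO₃⁻ addition (labelling fraction
ε of the nitrate pool), random pairing of reduced N atoms into N₂
implies, from the production rates p₂₉ and p₃₀ of ²⁹N₂ and ³⁰N₂:

    D15   = p29 + 2·p30             (denitrification of labelled NO3⁻)
    D14   = D15 · p29 / (2·p30)     (denitrification of unlabelled NO3⁻)
    D_tot = D14 + D15
    D_w   = D15 / ε                 (water-nitrate-fuelled, both isotopes)
    D_n   = D_tot − D_w             (coupled to in-situ nitrification)

Pairing consistency `p29² / (4·p28·p30) = 1` holds for pure
denitrification and rises above 1 under anammox (which makes ²⁹N₂ but
never ³⁰N₂); the package exposes this diagnostic alongside the
low-vs-high tracer concentration-independence check.

**DNRA.** Dissimilatory nitrate reduction to ammonium, from ¹⁵NH₄⁺
production scaled to the whole nitrate pool:
`DNRA = p¹⁵NH₄ · D_tot / D15` (gate p < 0.10).

**N₂ fixation.** Tracer incorporation into tissue:
`rate = APE / (A_N2 − A_PN0) · PN / Δt` per gram SFDW, with the
detection rule `APE > 2·SD(unlabelled reference)`.

**Comparisons and upscaling.** Treatment contrasts use an exact
Mann–Whitney U test (full enumeration, correct with ties, built for
n = 3–5 per group). Biomass-specific rates upscale to areal rates via
colony biomass (g m⁻²) and to population scenarios via density
(individuals m⁻²), and assemble into a bare-vs-colonized N budget with
a mass-balance residual.

## Worked example

Simulate four mussel microcosms at the default study conditions
(denitrification 58.4, DNRA 31.2, fixation 21.9 nmol N g⁻¹ h⁻¹,
ε = 0.6, 3% measurement noise) and run the inference chain:

```r
library(iptflux)
library(dplyr)

params <- true_parameters(noise_cv = 0.03, seed = 42)
geom <- tibble::tibble(vessel_id = paste0("ZM", 1:4), kind = "microcosm",
                       water_volume_L = 0.227, sediment_area_m2 = NA,
                       biomass_g = 0.037)

panel <- simulate_n2_series(params, paste0("ZM", 1:4)) |>
  isotopologue_slopes(geom) |>
  ipt_partition(epsilon = 0.6)
glance(panel)
#> # A tibble: 1 × 6
#>   n_vessels mean_D_tot mean_D_w mean_D_n prop_significant epsilon
#>       <int>      <dbl>    <dbl>    <dbl>            <dbl>   <dbl>
#> 1         4       59.1     59.2    0.452                1     0.6

dnra <- simulate_15nh4_series(params, paste0("ZM", 1:4)) |>
  production_rates(geom, analytes = "NH4_15N") |>
  dnra_total(panel)
dnra_to_denit(dnra, panel)
#> [1] 0.5349807
areal_from_specific(mean(dnra$dnra_total), 134)
#> [1] 4.237269

fix <- simulate_fixation_tissue(params) |>
  prepare_fixation_samples() |>
  fixation_rate() |>
  detect_incorporation()
select(fix, animal_id, ape, rate_nmol_g_h, detected)
#> # A tibble: 4 × 4
#>   animal_id     ape rate_nmol_g_h detected
#>   <chr>       <dbl>         <dbl> <lgl>
#> 1 ZM1       0.00188          22.5 TRUE
#> 2 ZM2       0.00178          21.3 TRUE
#> 3 ZM3       0.00210          25.2 TRUE
#> 4 ZM4       0.00178          21.3 TRUE
```

Reading it: mean total denitrification (59.1 nmol N g⁻¹ h⁻¹) recovers
the generating rate within noise; essentially all of it is fuelled by
water-column nitrate (`D_w ≈ D_tot`), as expected without sediment.
The DNRA:denitrification ratio is ~0.53, the upscaled areal DNRA ~4.2
µmol m⁻² h⁻¹ at 134 g SFDW m⁻², and all four animals show tissue ¹⁵N
enrichment above the 2×SD detection threshold with rates around the
true 21.9 nmol N g⁻¹ h⁻¹.

`run_pipeline("out_dir")` executes the whole chain (simulate → fluxes
→ IPT/DNRA/fixation → rank tests → budget) and writes stage CSVs plus
a JSON manifest; `inst/scripts/run_pipeline.R` wraps it for the shell.

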