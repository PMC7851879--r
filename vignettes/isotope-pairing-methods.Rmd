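---
title: "Methods: isotope-pairing rate inference and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-pairing rate inference and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iptflux)
```

This vignette is the package's own account of the models it
implements: what each estimator assumes, which tunable parameters
matter, what the synthetic-data generator does and does not emulate,
and where the design was genuinely open.

## Net fluxes from sealed incubations

A sealed core or microcosm accumulates (or consumes) a solute at a
rate assumed constant over the incubation, so concentration is linear
in time and the flux is the least-squares slope `b` scaled by the
enclosed geometry:

* cores: `F = b · V / A` in µmol m⁻² h⁻¹ (`V` water volume in L, `A`
  sediment area in m²; positive = release to the water);
* microcosms: `R = (b − b_ctrl) · V / W` in nmol g_SFDW⁻¹ h⁻¹ (`W`
  shell-free dry weight in g; `b_ctrl` the slope of the single
  water-only control).

The slope is taken over *all* time points rather than the endpoint
difference because the incubation-length rule that motivates the
design — stop before oxygen falls more than 20% below its initial
value — exists precisely to keep the change linear; when linearity
holds, the regression slope is the efficient estimator, and when it
does not, the endpoint difference would hide it. An endpoint mode
remains available through `run_config(flux_method = "endpoints")`.
Exceeding the drawdown limit sets an `O2_DRAWDOWN_EXCEEDED` flag, and
significant quadratic curvature (lack-of-fit test at α = 0.05, four or
more points) sets `NONLINEAR`; flags annotate results and never
suppress them, so rates and their quality can be reported separately.

Two numerical conventions in the slope machinery deserve note. With
exactly two samples the slope is the finite difference with SE 0 and
an undefined p-value. When the residual variance of a fit is at
floating-point roundoff (noiseless synthetic data, perfectly linear
series), the t-test is meaningless; the p-value is resolved by limit
to 0 for a nonzero slope and 1 for a flat series, so degenerate inputs
never produce NaN.

Subsampling with water replacement dilutes every later reading. The
correction adds back, at each withdrawal, the concentration jump
`f · (C_before − C_replacement)` (`f` = withdrawn fraction of vessel
volume) to all subsequent readings; the measurement at the withdrawal
time is taken before the exchange. This additive ledger is exact for
any number of sequential withdrawals and any production in between.

The single shared control per treatment contributes no SE to corrected
microcosm rates — a documented limitation of the one-control design,
not a modelling choice. Whether controls should correct rates or only
confirm absence of background activity is not decidable from the
design itself; correction is the default, switchable via
`run_config(control_correct = FALSE)`.

## Isotope pairing

After raising the ¹⁵N fraction of the water nitrate pool to ε,
denitrification draws nitrate atoms at random, so N₂ isotopologues are
produced binomially: a fraction `(1−ε)²` of pairs as ²⁸N₂, `2ε(1−ε)`
as ²⁹N₂, `ε²` as ³⁰N₂. Inverting this from the measured production
rates `p29`, `p30` (N₂ units):

* `D15 = p29 + 2·p30` — reduction of labelled nitrate (N-atom units);
* `D14 = D15 · p29 / (2·p30)` — reduction of unlabelled nitrate;
* `D_tot = D14 + D15`.

The partition into sources uses the convention `D_w = D15 / ε` — the
*total* (both-isotope) denitrification fuelled by water-column nitrate
— and `D_n = D_tot − D_w` for the component coupled to in-situ
nitrification. An alternative convention defines `D_w` from the
unlabelled pool only; the one used here is the standard reading and is
the only one that keeps `D_w + D_n = D_tot` as an identity. `D_n` is
floored at zero with a `DN_FLOORED` flag when noise pushes it
negative. A `p30` at or below `1e-12·|p29|` leaves `D14` undefined
(`UNDEFINED_D14`) instead of dividing by a numerical zero.

Significance gating follows the whole-dataset regression convention:
the production of each ¹⁵N species must increase significantly over
time (denitrification α = 0.05 on both isotopologue slopes, DNRA
α = 0.10). A failed gate *zeroes* the panel with a `NOT_SIGNIFICANT`
flag rather than dropping the vessel, so that rate ranges can honestly
start at zero. Per-vessel regressions produce the rate panels; the
pooled regression (each vessel centred on its own mean, one slope test
over all points) is the default gate, matching the reported use of all
data points for significance. Both modes are exposed because the
original description is ambiguous about which produced the per-animal
rates.

### Assumption checks

Two diagnostics guard the pairing assumptions:

1. **Tracer concentration-independence.** True rates must not depend
   on how much tracer was added. `independence_check()` compares mean
   `D_tot` (and DNRA) between the low and high tracer treatments and
   passes when the relative difference is within a tolerance (default
   0.25, configurable) — a deliberately loose band, since at n = 4
   vessels per level the sampling error of the means is itself of that
   order.

2. **Pairing consistency.** Random pairing implies
   `p29² / (4·p28·p30) = 1`. Anammox produces ²⁹N₂ (one labelled
   nitrite-derived atom paired with an unlabelled ammonium-derived
   atom) but never ³⁰N₂, driving the ratio above 1.

These two checks are *not* interchangeable, and the package treats the
second as the anammox diagnostic. Writing `D_p` for the true
denitrification pair rate and `A_p` for the anammox pair rate, the
generative model gives
`p29 = 2·D_p·ε(1−ε) + ε·A_p` and `p30 = D_p·ε²`, from which the IPT
estimate works out to

    D_tot_hat = (2·D_p + A_p)² / (2·D_p)

— biased upward by anammox, but with no ε term at all. The bias is
identical at every labelling fraction, so comparing `D_tot` across
tracer levels can never expose anammox under this model; only the
pairing-consistency ratio (which equals
`(2u + A_p)² / (4u(u + A_p))` with `u = D_p(1−ε)`, strictly above 1
whenever `A_p > 0`) can. The test suite asserts exactly this pair of
behaviours: independence holds across ε ∈ {0.3, 0.6, 0.9} with and
without anammox, and the consistency ratio separates the two regimes.

### Anammox from the ¹⁵NH₄⁺ treatment

With the ammonium pool labelled at fraction `f_a` and nitrate
unlabelled, denitrification produces only ²⁸N₂, so any ²⁹N₂
production is attributable to anammox:
`AMX = p29 / f_a` N₂ pairs h⁻¹ (`2·p29/f_a` N atoms). This is the
minimal estimator consistent with the treatment design; ³⁰N₂
production in that treatment, which would indicate coupled processes,
is reported but not interpreted. Detection requires a positive slope
significant at α; undetected anammox is reported as zero, and
correcting `D_tot` for detected anammox is a configuration option
(`anammox_correct`), off by default because it was assumed negligible
in the sediments this design comes from.

## DNRA

DNRA is measured as ¹⁵NH₄⁺ production during a ¹⁵NO₃⁻ incubation.
Assuming DNRA and denitrification draw on the same nitrate pool, the
labelled production scales to the whole pool by the ratio of total to
labelled nitrate reduction:

    DNRA_tot = p15NH4 · D_tot / D15

which satisfies `DNRA_tot · D15 = p15NH4 · D_tot` exactly and reduces
to `DNRA_tot = p15NH4` when the pool is fully labelled. The
DNRA:denitrification ratio is aggregated across vessels as
ratio-of-means by default (the aggregation that matches budget
upscaling); mean-of-ratios is available, because with per-vessel
pairing the two differ and the original reporting could reflect
either.

## N₂ fixation

The single-endpoint incorporation model: tissue atom% excess
`APE = A_PN(t) − A_PN(0)` over the source gradient gives the fraction
of the tissue N pool renewed from dissolved N₂,

    rate = APE / (A_N2 − A_PN(0)) · PN / Δt

per gram SFDW (nmol N g⁻¹ h⁻¹). `A_PN(0)` and its SD come from
unlabelled reference animals; incorporation is detected when
`APE > k·SD` with `k = 2` (strict inequality). Under a Gaussian null
this filter has a one-sided false-positive rate of
`1 − Φ(2) ≈ 2.28%`, which the test suite verifies by simulation at
10⁵ draws. δ¹⁵N values convert to atom% with the atmospheric ratio
0.0036765. Dilution of the enriched water by water carried inside the
animal is ignored (assumption); the source atom% is an input, not
derived from stock preparation.

## Exact rank test

Treatment contrasts at n = 3–5 vessels per group need exact
inference: normal-approximation p-values are unreliable there, and the
attainable significance levels are coarse (at 4 vs 4 the smallest
two-sided p is 2/70 ≈ 0.0286). `mann_whitney_exact()` enumerates all
`C(n1+n2, n1)` assignments of the pooled observations — ties included
naturally via average ranks over the observed multiset — and reports
`2·min(tail)` capped at 1, without mid-p. Enumeration is the default
up to `n1+n2 = 16`; beyond that the tie-corrected normal approximation
with continuity correction takes over. The test suite checks the
enumeration against an independently coded brute-force oracle for all
group sizes up to 6 and against the classical exact distribution in
tie-free cases.

## Upscaling and the nitrogen budget

All upscaling is linear: biomass-specific rates × areal biomass
(g m⁻²) / 1000 give µmol m⁻² h⁻¹; per-individual rates × density
(individuals m⁻²) / 1000 extrapolate over population scenarios. The
density extrapolation supports both a directly measured per-individual
rate and biomass-specific × mean individual biomass; the latter is the
default because all of its inputs are routinely reported.

The budget table joins bare and colonized areal rates per process,
computes the colonization increment, attaches the upscaled holobiont
contribution, and reports the holobiont share of each increment. Every
entry is carried from exactly one upstream number, never recomputed. A
per-condition mass-balance residual is defined on the benthic
compartment:

    residual = N2_fixation − (D_w + D_n) − (NH4 + NOx + DON effluxes)

DNRA is excluded because it transforms nitrogen inside the compartment
without crossing the sediment–water boundary; a self-consistent set of
rates balances to zero.

## The synthetic-data generator

The generator produces data with exactly the statistical structure the
estimators assume, so that every inference stage has a ground-truth
oracle:

* linear accumulation of every analyte at a constant true rate;
* binomial isotopologue pairing at the configured ε, anammox routed to
  ²⁸/²⁹N₂ only (ammonium-derived atom unlabelled under ¹⁵NO₃⁻
  treatments, labelled at `f_a` under the ¹⁵NH₄⁺ treatment);
* ¹⁵NH₄⁺ production at `dnra_a · ε`;
* tissue enrichment at `fix_a · Δt · W / (PN·1000) · (A_N2 − A_PN0)`;
* i.i.d. Gaussian measurement noise on concentrations, with SD equal
  to `noise_cv` times the net signal range of each analyte (5% by
  default). Noise sits on measurements, not on rates, matching the
  fixed-rate + instrument-noise model behind single-vessel regression.

Defaults are the study conditions this package was built around: rates
58.4 / 31.2 / 21.9 nmol N g⁻¹ h⁻¹ (denitrification / DNRA /
fixation), ε = 0.6, a 227 mL microcosm with a 37 mg SFDW animal
sampled at 0, 3, 6 and 8 h, cores of 8.4 cm inner diameter with a
16 cm water column sampled over 4 h, and an ambient dissolved N₂ pool
of 470 µM split at natural abundance. Where the source material states
no value the defaults are chosen once on physical grounds:
`f_a = 0.85` (a 6.3 µM ¹⁵NH₄⁺ addition into ~1 µM ambient ammonium),
dissolved-N₂ source enrichment 50 atom% (fixation microcosms are
filled entirely from a ³⁰N₂-enriched stock, so the dissolved pool is
strongly enriched — consistent with enrichment detectable in every
incubated animal), tissue natural abundance 0.3663 atom% with
SD 0.0002 (≈0.5‰, homogenised ground tissue), and 10% tissue N
content.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: nitrate concentration gradients and
diffusion in sediment, time-varying rates, N₂ ebullition or headspace
exchange, autocorrelated instrument drift, non-Gaussian outliers, and
any coupling between processes beyond the shared nitrate pool.
Parameter-recovery results certify the estimators, not the field
protocol.

## Problem sizes and reproducibility

The validation workloads are sized for interactive runs: 500 noisy
replicates for parameter recovery (mean recovered rate within 3
Monte-Carlo SEs of truth), 10⁵ draws for the detection-filter
false-positive rate, 300 replicates for the rank-test level
calibration, and full enumeration oracles up to 6 + 6 observations.
All simulators take explicit integer seeds, restore the caller's RNG
state, and produce bit-identical output for identical parameters;
`run_pipeline()` records seed, configuration and file digests in a
JSON manifest, and rerunning with the same seed reproduces every
output digest.

## Known limitations

* The `D_w = D15/ε` convention assumes a well-mixed water nitrate pool
  at a single, known ε; vertical ε gradients in sediment bias `D_n`.
* The DNRA scaling inherits any bias in `D_tot/D15`, e.g. from
  undetected anammox.
* One shared control per treatment leaves control uncertainty
  unpropagated.
* The anammox estimator attributes *all* ²⁹N₂ production in the
  ¹⁵NH₄⁺ treatment to anammox; nitrification of labelled ammonium
  followed by denitrification would inflate it.
* Upscaling assumes rates measured on individuals transfer linearly to
  colonies and populations; density extrapolation beyond the measured
  biomass range is exactly that — extrapolation.
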