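---
title: "Methods: greenhouse-gas fluxes, isotopic pathways and carbon age in thaw ponds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: greenhouse-gas fluxes, isotopic pathways and carbon age in thaw ponds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondgas)
```

`pondgas` implements the complete measurement-to-budget chain used in
limnological greenhouse-gas studies of small permafrost thaw ponds: dissolved
CO~2~ and CH~4~ from headspace equilibration, wind-based diffusive fluxes with
a small-pond chamber correction, ebullition (bubble) fluxes from funnel traps,
stable-isotope attribution of the methanogenic pathway, radiocarbon carbon-age
apportionment, pond-type contrasts, and landscape upscaling. Two pond types
organise the analysis throughout: *polygonal* ponds (stable, atop low-centred
peat polygons) and *runnel* ponds (shallow troughs over degrading ice wedges,
fed by eroding old peat).

This vignette documents the models, the tunable parameters with their units
and defaults, the numerical choices, and what the synthetic campaign generator
does and does not emulate.

## Dissolved gas from headspace equilibration

A water sample of volume $V_w$ (default 2 L) is shaken to equilibrium with a
small headspace $V_h$ (default 20 mL) of ambient air; a gas chromatograph
reads the headspace mixing ratio afterwards. The original dissolved
concentration follows from Henry's law plus a mole balance over the two
phases:

$$C_0 = K_H(T)\,p_{eq} + (p_{eq} - p_{air})\,\frac{V_h}{V_w R T_K},$$

where $p_{eq}$ and $p_{air}$ are the final-headspace and ambient partial
pressures and $K_H(T)$ is the solubility adjusted to the water temperature by
the van 't Hoff relation

$$K_H(T) = K_H^{298}\exp\!\left[C\left(\tfrac{1}{T_K}-\tfrac{1}{298.15}\right)\right].$$

Defaults: $K_H^{298}$ = 3.4 × 10^-2^ mol L^-1^ atm^-1^ ($C$ = 2400 K) for
CO~2~ and 1.4 × 10^-3^ mol L^-1^ atm^-1^ ($C$ = 1700 K) for CH~4~ — the
standard freshwater values. All constants live in one editable bundle
(`gas_constants()`, or a plain-text file via `read_gas_constants()`); nothing
is hard-coded in the operations.

Both the full mass balance and the pure Henry's-law readback
(`method = "henry_only"`) are exposed; mass balance is the default. With a
20 mL headspace over 2 L of water the headspace term is small (of order 1%),
but the balance costs nothing and removes the approximation. Readings
implying a negative $C_0$ are flagged invalid and kept with their negative
value rather than clamped, so QC reports can count them.

```{r headspace}
ch4 <- gas_species("CH4")
headspace_to_dissolved(ch4, water_volume_L = 2, headspace_volume_L = 0.02,
                       temperature = 10, ppm_final = 250, ppm_air = 1.8)
```

## Diffusive flux

Air–water exchange follows the boundary-layer model

$$F_d = c \cdot k\,(C_{sur} - C_{eq}),$$

with $C_{eq}$ the concentration in equilibrium with the atmosphere (default
mixing ratios 390 ppm CO~2~, 1.8 ppm CH~4~; configurable) and $k$ the gas
transfer velocity. $k$ is built from the wind-based Cole–Caraco model at the
Schmidt-number-600 reference,

$$k_{600} = 2.07 + 0.215\,U_{10}^{1.7} \quad (\mathrm{cm\,h^{-1}}),$$

rescaled to the gas and temperature of interest by
$k = k_{600}(Sc/600)^{-n}$, with $n = 2/3$ below 3 m s^-1^ and $n = 1/2$ at
or above it (the boundary itself uses 1/2 — a documented tie-break). Schmidt
numbers come from the freshwater third-order temperature polynomials, which
put Sc(CO~2~, 20 °C) at ~600, the normalisation point. $U_{10}$ is averaged
over the 2 h preceding each gas sample (`wind_window_mean()`; an empty window
is an explicit missing-data error, not an NA).

Wind models overestimate transfer on small, sheltered, thermally stratifying
ponds, where daytime buoyancy suppresses near-surface turbulence. A
multiplicative correction factor $c$ (default 0.2458) absorbs this; it is the
zero-intercept least-squares slope of directly measured floating-chamber CO~2~
fluxes on wind-model fluxes (`fit_correction_factor()`; an intercept mode
exists for sensitivity analysis). The correction is through the origin because
it represents a pure rescaling of $k$; the same factor is applied to CH~4~ by
default (it corrects the physics of $k$, not the gas), overridable per
species. Positive flux is emission; undersaturated water gives negative flux
(the pond is a sink — the typical polygonal-pond CO~2~ state).

Units compose directly: µM × m d^-1^ = mmol m^-2^ d^-1^, with
cm h^-1^ × 0.24 = m d^-1^.

## Ebullition

Bubbles collected by a submerged funnel over duration $t$ give

$$F_e = \frac{V \cdot f_{CH_4}}{A \cdot MV(T) \cdot t},$$

with $V$ the gas volume, $f_{CH_4}$ the bubble CH~4~ volume fraction, $A$ the
funnel area (default 0.3526 m^2^) and $MV = RT_K/P$ the ideal-gas molar
volume at ambient air temperature. Micro-ebullition is *not* folded into the
diffusive term, so diffusive estimates remain conservative. No bubble
dissolution during rise is modelled (ponds are < 1.5 m deep).

## Methanogenic pathway from stable isotopes

Two classifiers, usable independently or together:

* **CD diagram** (`classify_pathway_cd()`): rectangular regions in
  (δ^13^C-CH~4~, δD-CH~4~) space. Defaults follow the standard freshwater
  convention — acetoclastic δ^13^C ∈ [−65, −50] ‰, δD ∈ [−400, −250] ‰;
  hydrogenotrophic δ^13^C ∈ [−110, −60] ‰, δD ∈ [−250, −150] ‰. Membership
  in both regions → `mixed`; in neither → `indeterminate`. Classification
  without δD is refused with an explicit reason: the pathways' δ^13^C ranges
  overlap, and only the deuterium signature rules out the hydrogenotrophic
  alternative. Rectangles (not polygons) were chosen for testability; the
  boundary set is configuration, recorded in every output row, because
  published CD diagrams differ slightly in where they draw the fields.
* **Apparent fractionation** (`classify_pathway_alpha()`):
  $\alpha_C = (\delta^{13}C\text{-}CO_2 + 1000)/(\delta^{13}C\text{-}CH_4 + 1000)$,
  with acetoclastic [1.040, 1.055], hydrogenotrophic (1.055, 1.090], and
  `oxidation_affected` below 1.040 — methanotrophy enriches residual CH~4~ in
  ^13^C and drives the apparent fractionation down. Bounds configurable.

Both classifiers are deterministic and total on the valid domain; instrument
precision (±0.2 ‰ C, ±3 ‰ D) belongs to the data generator, never to the
classifier — there are no probabilistic calls. Partial oxidation of diffusing
CH~4~ is probed separately by `oxidation_regression()` (OLS of δ^13^C-CH~4~
on surface O~2~; a positive slope is the oxidation signature).

```{r isotopes}
classify_pathway_cd(-60, -330)
classify_pathway_alpha(apparent_fractionation(-15, -60))
```

## Radiocarbon: age and old-carbon apportionment

Δ^14^C (‰) converts to fraction modern with the reporting-convention decay
correction for the measurement year ($\lambda = 1/8267$ yr^-1^):

$$F_m = \frac{\Delta^{14}C/1000 + 1}{\exp[\lambda(1950 - y)]},$$

and to a conventional age by $t = -8033\ln F_m$; $F_m \ge 1$ is post-bomb and
flagged modern. A sample is classed `modern` if post-bomb or younger than a
60-yr window, else `old`. Old-carbon content is apportioned by linear
two-endmember mixing in $F_m$ space,
$f_{old} = (F_m^{mod} - F_m)/(F_m^{mod} - F_m^{old})$, with defaults
$F_m^{mod} = 1.05$ (carbon recently fixed from the post-bomb atmosphere; the
exact contemporary value is site- and year-dependent, so it is configuration,
and $f_{old}$ shifts by roughly 0.02 per 0.01 change in it) and
$F_m^{old} = e^{-3670/8033} \approx 0.633$, the basal-peat age of the eroding
deposit. Samples outside the endmember interval are clamped to [0, 1] with a
warning flag. The mixing fraction formalises the qualitative "more old
carbon in runnel ponds" comparison; calibration to calendar years is out of
scope.

## Group contrasts and landscape upscaling

Welch's *t* (unequal variances, Welch–Satterthwaite df, two-sided) and the
paired *t* are implemented from their formulas so the pipeline is
self-contained and verifiable against independent oracles; tests cross-check
them against `stats::t.test`. Two-sided throughout; no multiple-testing
correction is applied (the report records the number of tests performed).
Degenerate paired differences (zero spread, nonzero mean) are flagged rather
than silently assigned a p-value.

Landscape shares combine per-type open-water area fractions with per-type
mean areal fluxes: $s_i = a_i f_i / \sum_j a_j f_j$. Area fractions need not
sum to one (lakes and other surfaces may be excluded); shares always do. With
the default areas (runnel 44%, polygonal 27% of valley open water) and equal
fluxes the shares reduce to 44/71 and 27/71.

## The synthetic campaign generator

`generate_campaign()` draws a full field campaign — pond, wind, headspace,
funnel, isotope and radiocarbon tables plus a ground-truth table — as a pure
function of its seed. It emulates the *statistical structure* of a short
Arctic summer campaign:

* **Design**: 33 polygonal and 58 runnel ponds (one discrete daytime sample
  each, 09:00–16:00), funnels on two polygonal ponds (8 collections each,
  12–32 h; funnels cannot be installed in the narrow runnels), 19 diffusive
  and 4 ebullition isotope samples, 10 radiocarbon samples.
* **Concentrations** are lognormal per group — positive and right-skewed,
  consistent with group sd exceeding the mean for CH~4~ — moment-matched
  (`lognormal_from_mean_sd()`) to CO~2~ 119 ± 124 µM (runnel) vs
  9.6 ± 8.9 µM (polygonal) and CH~4~ 4.1 ± 4.7 vs 1.3 ± 1.7 µM.
* **Headspace readings** are forward-simulated from the same closed-form
  partition balance the inversion solves, with 2% multiplicative GC noise
  (typical FID precision; lognormal, unit mean).
* **Wind** is hourly, lognormal, mean 4 m s^-1^ (typical open-tundra summer
  wind) with the campaign's 45% coefficient of variation, drawn
  independently hour to hour.
* **Ebullition** event fluxes are lognormal truncated at 2.13 mmol m^-2^
  d^-1^ (the observed maximum; only a range is known, so truncation encodes
  the cap) with bubble CH~4~ fractions uniform on [1.5%, 32%].
* **Isotopes** are drawn from the interior of the configured pathway regions
  (margins of ≥5 measurement sd), with instrument noise ±0.2 ‰ C and ±3 ‰ D;
  the default mixture is 100% acetoclastic, the summer condition of the
  emulated system. The optional O~2~–δ^13^C oxidation coupling
  (`oxidation_slope`) defaults to 0 so that pathway ground truth is exactly
  recoverable; the oxidation regression is exercised in tests by direct
  simulation with a known slope instead.
* **Radiocarbon** samples mix the two endmembers with uniform old fractions —
  polygonal [0, 0.03], runnel [0.03, 0.12], encoding the higher old-carbon
  supply from eroding peat in runnels — plus 2.8 ‰ AMS noise (middle of the
  stated 2.5–3.1 ‰ precision range).

What the generator does *not* emulate: temporal autocorrelation of repeated
within-pond measures (draws are independent), mechanistic CH~4~
production/oxidation dynamics, spatial pond geometry, diel cycles in
temperature and stratification, and covariance between concentration and
wind. Passing recovery tests therefore demonstrates that the *computational
chain* is correct under the study's statistical conditions — not that the
generator is a faithful physical model of any particular pond.

Setting all noise levels to zero makes the pipeline's report equal the ground
truth to relative error < 10^-9^ at every stage ("closure"), which is the
package's strongest end-to-end contract.

```{r campaign}
camp <- generate_campaign(campaign_config(seed = 7))
rep <- run_report(camp)
rep
```

## Numerical choices and degenerate inputs

* Temperature domains are enforced, not extrapolated: Henry constants on
  (−2, 40) °C, Schmidt polynomials on [0, 30] °C (their fitted range).
* The headspace inversion is closed-form (no iteration); tests verify it
  against an independent root-finding equilibration oracle to < 10^-9^
  relative error on 1000 random cases.
* The Schmidt exponent switches at exactly 3 m s^-1^; the boundary is
  assigned to −1/2.
* Diurnal variability defaults to the coefficient of variation
  (100·sd/mean), with (max−min)/mean as an explicit option — the summary
  statistic is not uniquely determined by convention, so both are exposed.
* All-zero model fluxes, constant O~2~, equal endmembers, empty wind windows
  and negative inversions each raise named errors (or carry flags) rather
  than propagating NaN.
* Simulation sizes in the test suite (1000 inversion cases, 500 calibration
  replicates, 200 campaigns for the contrast study, 2000 null replicates,
  10^4^ radiocarbon draws) were chosen so Monte-Carlo error is well below
  each assertion's tolerance.

## Interfaces

The package is function-first: `generate_campaign()` → `run_report()` covers
the whole chain, and each stage is exported for standalone use on field CSVs
(`read_headspace_csv()`, `read_wind_csv()`, `read_funnel_csv()`,
`read_isotope_csv()`, `read_radiocarbon_csv()`). `write_campaign()` /
`run_report(out = ...)` emit per-stage CSVs with full provenance columns
(k600, k, Sc, correction, boundary-set id) plus a manifest recording seed,
version and configuration. `scripts/acceptance.R` recomputes the headline
quantities from scratch and writes them as JSON.

## Known limitations

* No surface-renewal or heat-flux-based transfer models; the chamber
  correction stands in for that physics as a single factor.
* No carbonate-system speciation: "dissolved CO~2~" is free CO~2~ from the
  headspace, not DIC.
* No salinity correction (ponds are fresh) and no altitude correction
  (near sea level).
* Rayleigh-type oxidation-fraction estimation and IntCal calendar
  calibration are out of scope.
* The upscaling operation is general but only as good as the supplied area
  fractions and mean fluxes; it ignores within-type flux–area covariance.
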