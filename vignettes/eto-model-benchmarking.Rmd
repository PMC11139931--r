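---
title: "Methods: benchmarking empirical ET0 models on monthly climate normals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking empirical ET0 models on monthly climate normals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etobench)
```

## The procedure

`etobench` runs a model-comparison study on one year of monthly climate
normals: 12 records of temperature extremes, rainfall, humidity extremes,
wind run, bright sunshine and class-A pan evaporation. The pipeline is

1. **Derive the meteorology** (`derive_met()`). Each month is represented
   by the 15th of the month on a non-leap calendar; extraterrestrial
   radiation Ra and daylight length N come from the standard astronomical
   formulas (solar declination, sunset hour angle, inverse relative
   Earth–Sun distance), surface solar radiation from the
   Ångström–Prescott relation Rs = (a + b·n/N)·Ra, and net radiation from
   the FAO-56 shortwave/longwave balance. Saturation vapour pressure uses
   the Tetens form; the psychrometric constant follows atmospheric
   pressure at the site elevation.
2. **Compute the baselines**. Pan-derived ET₀ = Kpan·Epan with the
   Allen–Pruitt pan coefficient; and FAO-56 Penman–Monteith on the derived
   meteorology.
3. **Compute the 18 empirical models** from a registry
   (`model_registry()`), each in the unit dialect its coefficients were
   fitted in (Turc and Makkink consume Rs in cal cm⁻² day⁻¹, Caprio in
   kJ m⁻² day⁻¹, the rest in MJ m⁻² day⁻¹).
4. **Score every model against both baselines** with eight statistics
   (FAC2, MB, MGE, NMB, NMGE, RMSE, Pearson r, refined index of
   agreement), Taylor-diagram coordinates, and rankings under every key
   statistic.

The whole study is deterministic: identical inputs give identical outputs.

## Model assumptions

All computations are monthly: a climate normal is treated as a typical day
of its month, so ET₀ is in mm day⁻¹ throughout and no sub-monthly
variability enters. Soil heat flux G is taken as zero — the usual daily
convention, retained for monthly normals where the storage term of a
shallow grass surface is small against Rn (configurable via
`eto_conventions(g_soil = )`). The reference surface is FAO-56 grass:
albedo 0.23, latent heat λ = 2.45 MJ kg⁻¹ fixed.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `angstrom_a`, `angstrom_b` | 0.25, 0.50 | – | FAO-56 defaults where no local sunshine–radiation calibration exists; they reproduce the packaged station's reproducible radiation-model values |
| `pan_fetch` | 100 | m | the pan coefficients implied by the packaged observed series (0.78–0.85) match the Allen–Pruitt regression at F ≈ 100 |
| `albedo` | 0.23 | – | FAO-56 grass reference |
| `latent_heat` | 2.45 | MJ kg⁻¹ | FAO-56 convention; temperature dependence is below the precision of monthly normals |
| `gamma_override` | none | kPa °C⁻¹ | γ is computed from elevation (0.0517 at 2218 m). A fixed sea-level-like value 0.0677 circulates for this station; it is inconsistent with the elevation, so it is offered only as an override. Both FAO-PM series stay within 0.3 mm day⁻¹ of the published row; the elevation-based one is closer (max deviation 0.19 vs 0.42) |
| `hargreaves_exponent` | 0.5 | – | the classic Hargreaves–Samani exponent on the diurnal range; it reproduces the published January value (3.2), whereas the 0.517 variant gives 3.34 |
| `ea_method` | `dual_rh` | – | FAO-56 dual-RH actual vapour pressure; `mean_rh` selectable |
| `rh_mode` | `mean` | – | which RH the single-humidity models (Schendel, Ivanov) consume; neither convention reproduces the published Schendel row, so the choice is exposed |
| `kpan_variant` | `allen_pruitt` | – | the standard regression; a circulated variant with a 3.31·10⁻⁴ wind coefficient and (ln F)⁻⁴ interaction is kept behind a flag for audit but is dimensionally inconsistent with the published coefficients |
| `ioa_c` | 2 | – | the standard scaling constant of the refined Willmott index |

## Numerical choices and degenerate inputs

- **Clamps.** The sunset-hour-angle argument is clamped to [−1, 1] so polar
  latitudes return Ra = 0 and N = 0 rather than NaN. The sunshine ratio
  n/N is clamped to 1. The relative-shortwave ratio Rs/Rso is clamped to 1
  and the net longwave loss floored at 0, which keeps 0 ≤ Rn ≤
  (1 − α)Rs even for Rs = 0. Kpan is clamped to the plausible 0.3–1.1.
- **Floors.** Model outputs are floored at 0; the linear Irmak/Tabari fits
  can go negative at cold extremes, and each flooring emits a warning so
  audits can see it.
- **Errors, not NaNs.** Pearson r and the index of agreement are undefined
  for constant series and raise errors; Tmax < Tmin, RH outside
  0 ≤ min ≤ max ≤ 100, fetch ≤ 1 m and similar physical violations are
  rejected with the offending month named.
- **Tie-breaks.** `rank_models()` orders by the key statistic (descending
  for FAC2, r, IOA; ascending magnitude for the error statistics), then by
  ascending RMSE, then model id — a total, deterministic order. IOA
  descending is the default key because it reproduces both published
  performance orderings exactly; no ordering statistic is stated alongside
  those orderings, so this is the package's inference.
- **FAC2 with zero observations.** A pair with O = 0 cannot lie within a
  factor of two and counts as outside.

## The Penman–Monteith grouping

The combination equation is implemented in its canonical FAO-56 grouping
(radiative and aerodynamic terms in the numerator, Δ + γ(1 + 0.34 u₂) in
the denominator). Circulated renderings of the equation sometimes drop the
parentheses; the canonical grouping is used because it reproduces the
published monthly FAO-PM series to within 0.2 mm day⁻¹.

## What the synthetic generator emulates — and what it does not

`generate_monthly_climate()` produces 12 months with: sinusoidal annual
cycles for Tmax (peak April) and Tmin (peak May), a monsoon block
(June–September by default) with boosted minimum humidity (+21 points) and
wind (+3.2 km h⁻¹), sunshine decreasing linearly with minimum humidity,
pan evaporation increasing with Tmax and sunshine, and seeded Gaussian
noise on every variable. Defaults imitate the packaged tropical-highland
normals (Tmax 17.6–22.1 °C, monsoon RHmin near 80 %, ~74 % of rain in the
monsoon). Outputs are clipped into physical ranges, so every generated
climate passes validation for any seed.

It does **not** emulate: inter-annual variability (each draw is one
synthetic climatology, not 60 years of weather), rainfall occurrence
processes, autocorrelated noise, or the fine covariance structure between
humidity, cloud and wind. Passing property tests on generated climates
therefore demonstrates numerical robustness and ordering behaviour across
realistic magnitudes — not calibration to any real station beyond the
packaged one.

## Known limitations

- Six published monthly series (Schendel, Ivanov, Papadakis, Makkink,
  Priestley–Taylor, Abtew) are not reproducible from the published climate
  normals under any standard unit or humidity convention tried; the
  original radiation source and humidity granularity behind them are
  unpublished. The packaged per-model series is therefore the
  authoritative input for the metric layer, and the model layer pins only
  the reproducible rows (Hargreaves–Samani, Kharrufa, Trajkovic, Berti,
  Jensen–Haise, Irmak-Rs, Caprio, Jones, Turc, Tabari, and Blaney–Criddle
  January–October; the published Blaney–Criddle November/December cells
  are inconsistent with the formula that reproduces the other ten months
  and with the Kharrufa cells computed from the same daytime-percentage
  table).
- The published evaluation tables were computed on unrounded monthly
  series; recomputing from the rounded published series shifts MGE, RMSE
  and IOA in the second decimal. Tests therefore pin the rounding-stable
  cells (FAC2, MB, NMB, r) exactly and verify the rest through metric
  identities and oracle equivalence.
- The driver correlations use the monthly normals; correlations quoted
  from finer-grained (e.g. seasonal) aggregation differ in the second
  decimal (Tmax: 0.883 here).
- The Trajkovic model is implemented literally (Ra in MJ m⁻² day⁻¹, no
  latent-heat division) because that literal reading reproduces its
  published 5.7–8.1 mm day⁻¹ range — the model's characteristic
  overestimation at humid tropical sites.

## Problem sizes

The test suite exercises: 1000 random inputs for the primitive-vs-oracle
equivalences, 1000 random series pairs for the metric-vs-oracle
equivalence, 1000 seeds for generator validity, 50 seeded synthetic
climates × 18 models for the finite/non-negative property, and 12-month
fixtures everywhere else. These sizes make the whole suite run in about a
minute on one core while keeping the Monte-Carlo assertions stable.

## A minimal session

```{r example}
study <- run_study(table1_fixture())
study
round(subset(study$eto, model_id == "berti")[, -(1:2)], 2)
rank_models(table4_fixture()[table4_fixture()$category == "temperature", ],
            key = "ioa")$model_id
```
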