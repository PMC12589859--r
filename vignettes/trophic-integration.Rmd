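---
title: "Modelling the trophic integration of non-native plants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the trophic integration of non-native plants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophinet)
```

## The question and the quantity

When a plant species establishes outside its historical range, the
microherbivores of the recipient region — leaf miners, gall formers,
borers, eriophyid mites and plant-pathogenic fungi — do not ignore it
forever. `trophinet` operationalises *trophic integration* as
**microherbivory richness**: the number of distinct microherbivore
species documented on a plant. Working from a bipartite interaction edge
list plus plant attributes, the package asks (i) how much richness
non-native plants support relative to natives, (ii) which of four
predictors — introduced range size, time since introduction,
geographic proximity of the native range, relatedness to the native
flora — drives richness among non-natives, and (iii) whether the
microherbivores of well-integrated non-natives are disproportionately
generalist.

Richness in such compilations is heavy-tailed: most plants have one
documented microherbivore, a few have dozens. All models therefore use
`log10(richness)` as the response, and only interacting plants exist in
the data (richness ≥ 1 by construction).

## The models

Two REML linear mixed models, both with a plant-family random intercept
to absorb phylogenetic non-independence at the coarsest level:

* **Origin model** `log10(richness) ~ origin * woodiness + (1 | family)`.
  Woodiness is included because woody plants support systematically more
  microherbivores, and origin and growth form are confounded in most
  floras.
* **Drivers model** (non-natives only)
  `log10(richness) ~ woodiness * (log10 AOO + intro_year +
  centroid_dist + relatedness) + (1 | family)`. Every predictor
  interacts with woodiness because the richness–range scaling is steeper
  in woody plants.

Slopes are reported per original unit (per log10 km², per calendar
year, per km). Internally year and distance are centred and rescaled
(centuries, 10³ km) for optimizer stability; estimates and standard
errors are transformed back exactly, so the reported fit is invariant to
this choice.

Fixed-effect inference uses Wald z-tests by default. A Satterthwaite
mode (via lmerTest) is available through `p_values = "satterthwaite"`;
the two agree to several decimals at the sample sizes involved here, and
no downstream quantity depends on p-values.

### Variance decomposition

`r2_decomposition()` uses the fixed-predicted-value definition:
σ²_fixed is the variance of `Xβ` over the fitted sample, marginal
R² = σ²_fixed / (σ²_fixed + σ²_family + σ²_residual), conditional R²
adds σ²_family to the numerator. The **semi-partial R²** of a predictor
group (the predictor plus its woodiness interaction) is the marginal R²
of the full model minus that of a model refitted *without* the group, on
identical rows, both by REML — a variance-based definition rather than
a likelihood-ratio one, chosen to match the marginal-R² scale.
Semi-partials quantify uniquely attributable variance and do not sum to
the full marginal R² when predictors are correlated. Small negative
values (possible because REML variance components change between fits)
are truncated to zero and reported. Confidence intervals come from a
parametric bootstrap: responses are re-simulated from the fitted model
(fixed effects + family effects + residual noise) and every model is
refitted per draw; 500 draws give stable 95% percentile intervals and
are the default, tests use far fewer.

### Back-transformations and crossover thresholds

On a log10 response, a range-size slope β means a tenfold range increase
multiplies richness by `10^β` (`backtransform_per_decade()`); a year
slope β means a 100-year earlier introduction multiplies it by
`10^(-100β)` (`backtransform_per_century()`); a distance contrast Δ km
changes it by `(exp(βΔ) − 1) × 100` percent
(`distance_effect_percent()`), evaluated directly from the slope.

`crossover_threshold()` inverts the drivers model: holding the other
covariates at reference values, it solves
`predicted log10 richness = log10(target)` for one predictor. The
prediction is linear in the predictor, so the inversion is closed-form;
a consistency test checks the round trip to 1e-6 on the log scale. The
conditioning point is genuinely open — we use the covariate means of
the fitted non-native sample with relatedness at its modal level, which
makes the threshold "the value at which an otherwise-average non-native
matches the target". Thresholds are extrapolations whenever the target
lies outside the fitted support and should be read with the usual
caution (the default-regime example in the README illustrates how far
out they can land).

`residence_years()` turns a crossover introduction year into a residence
time against a reference year (default 2025).

## Covariate engineering choices

Several small rules needed fixing where a verbal description leaves
room; each is a deliberate package-level decision:

* **Woodiness gap-fill** (`fill_woodiness()`): unknown species get the
  modal observed state of their genus. A tie leaves the species
  unknown — the mode is simply undefined at a tie, and an alphabetical
  tie-break would bias toward one growth form. Observed states are never
  overwritten.
* **Earliest introduction** (`earliest_introduction()`): minimum year
  per species over regional first records; species whose earliest record
  is ≤ 1492 are excluded ("introduced after 1492"), so the cutoff year
  itself is out.
* **Proximity exclusion** (`apply_proximity_exclusion()`): strictly
  `< 2500 km` is removed; a centroid exactly at 2500 km is retained.
  The exclusion guards against artificial proximity when centroids of
  disjunct multi-continent ranges average to a point near the focal
  region.
* **Centroid averaging** (`native_centroid()`): unweighted arithmetic
  mean of region-centroid latitudes and longitudes, matching the
  country-centroid-averaging convention. Longitudes are not wrapped, so
  ranges straddling ±180° can average to a misleading point — a known
  limitation; none of the synthetic regions straddle the antimeridian.
* **Great-circle distance** (`great_circle_km()`): haversine on a sphere
  of radius 6371.0088 km (mean Earth radius). Geodesic-ellipsoid
  distances differ by < 0.3%, negligible at the precision used.
* **AOO** (`compute_aoo()`): occupied-cell count inside the focal region
  × cell area (default 2500 km²). Cells are abstract integer indices;
  no projection is performed, and a cell intersecting the region
  boundary counts in full.
* **Phagy classes** (`classify_phagy()`): monophagous (1 host species);
  oligophagous (> 1 species, ≤ 4 genera, 1 family); mesophagous (> 1
  genus, ≤ 3 families); polyphagous (otherwise). The oligophagous and
  mesophagous conditions overlap for one-family profiles with 2–4
  genera; rules apply narrow-to-broad, so those profiles are
  oligophagous. An enumeration test over all consistent count triples up
  to 50 host species confirms the classification is total and
  single-valued.
* **Host breadth** is computed on the *full* dataset before any
  integration filtering, so a microherbivore's generalism does not
  change when the plant set is restricted.
* **Integration filter** (`integration_filter()`): non-natives qualify
  with AOO strictly above 1.1 million km² (non-woody) or 270,000 km²
  (woody) — growth-form-specific because the richness–range slope is
  steeper in woody plants. Residence-time compositions use 50-year bins
  by default; the bin width is not empirically constrained, and empty
  bins are simply absent.
* **Missing data**: model fits use listwise deletion with a reported
  count; the pipeline manifest ledgers every dropped record (genus-only
  rows, duplicates, pre-cutoff introductions, proximity exclusions,
  unresolved woodiness).

## What the synthetic generator emulates

`generate_flora()` + `generate_interactions()` produce a study system
with the statistical structure the analysis assumes. The defaults *are*
the study conditions: 5751/1061 native and 2074/1379 non-native
non-woody/woody plants; slopes 0.218/0.308 per log10 km², −0.00097/
−0.0014 per year, −2.31e-5/−3.33e-5 per km; introduction years uniform
on 1493–2000; centroid distances uniform on 2654–17,523 km; occupied
cell counts log-uniform (AOO 2500 km²–5 × 10⁶ km²); family SD 0.15 and
residual SD 0.35 on the log10 scale; group intercepts calibrated once so
that mean richness lands near 4.1/6.2 (natives) and 1.8/2.2
(non-natives). The realised richness distribution then has mode 1 and a
long tail, as in real compilations.

Latent richness is rounded to the nearest integer and floored at 1 —
real data contain no zero-interaction plants, and the floor keeps
`log10` defined. Herbivore identities are assigned so that an expected
`specialist_fraction` (default 0.35) of herbivores have exactly one host,
attaching to native hosts with probability 0.9 (reproducing the
nested specialist-on-native pattern); multi-host herbivores draw 2+
hosts weighted by remaining plant capacity, 40% of them confined to one
family so that all four phagy classes arise. Each plant's realised
partner count equals its drawn richness exactly, which is what makes
generator bookkeeping usable as an oracle for the ingest and
specialisation modules.

The generator also writes realistic raw-file blemishes: synonym-aliased
plant names, genus-level records, duplicated rows, multiple regional
first records including spurious pre-1492 entries, and occurrence cells
outside the focal region. These exercise every cleaning rule end to end.

What it does **not** emulate: feeding-guild structure, literature
source counts, spatially autocorrelated sampling effort, and any
correlation between covariates (introduction year and range size are
independent in the generator, whereas they are correlated in real
floras). Passing tests therefore validate the machinery, not the
realism of any particular empirical estimate.

### Discretisation, censoring and the recovery regime

At realistic richness levels roughly half of all non-native plants sit
at richness 1, so `log10(max(1, round(10^η)))` censors the lower tail of
the latent variable η. A censored response attenuates fitted slopes —
in simulation at the default calibration by roughly 25–45% — exactly
as it would in any real dataset whose response is a small positive
integer. This is a property of the data regime, not an estimator bug.
Parameter recovery of the *fitting machinery* is therefore assessed in a
documented **recovery regime** (`synthetic_config(recovery = TRUE)`):
1000 non-native plants in 30 families with intercepts raised so mean
richness is ≈ 15–20 and the discretisation is negligible. Under that
regime each generating slope falls inside its fitted 95% CI in ≥ 90% of
20 seeds, and the deliberately null relatedness effect explains < 1% of
unique variance. The contrast between the two regimes is itself
informative: fold-type group contrasts are robust to the censoring,
slope magnitudes are not.

## Problem sizes and numerical choices

The test suite runs generators at 300–2000 plants and the recovery
experiment at 20 seeds × 1000 non-natives, sizes chosen to pin every
statistical property while keeping a full run in a couple of minutes;
the acceptance script adds one pipeline run at the full default
dimensions (~10⁴ plants, ~3.5 × 10⁴ associations). Singular family fits
(variance at zero) warn but do not fail, degenerate residuals warn in
the diagnostics, and all generation is bit-reproducible: one RNG stream
per module call, sub-seeded deterministically from `config$seed`.

## Known limitations

* No robust (heavy-tail-downweighting) mixed-model variant; the
  residual-normality summary (`residual_normality_summary()`) quantifies
  the deviation instead.
* Relatedness is binary at genus/family rank; no phylogenetic distances.
* The AOO abstraction ignores projection distortion and partial cells.
* Crossover thresholds condition on sample means; other conditioning
  points give other thresholds, and extrapolation beyond the fitted
  covariate support is unguarded.
* Antimeridian-straddling native ranges average incorrectly (flagged
  above); affected species should be excluded upstream.
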