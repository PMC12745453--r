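---
title: "Methods: landscape composition and health-behavior intensity at the plot scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape composition and health-behavior intensity at the plot scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkscape)
```

`parkscape` operationalises a plot-scale view of how park landscapes
support health behavior: a park is sampled as 30 m × 30 m plots, each
plot's visual composition is quantified from photographs, the health
behavior observed there is scored into intensity indices, linear models
link the two, and the fitted models are extrapolated over the whole park
on a fishnet grid. This vignette documents the model, its assumptions,
the tunable parameters, the numerical choices, and what the synthetic
data used by the test suite does and does not establish.

## Behavior intensity indices

Observed activity is coded with a 34-entry taxonomy whose leading digit
fixes the category: 1xx exercise (EB, 16 codes), 2xx leisure (LB, 11),
3xx social (SB, 7). Each record carries a participant count, and each
code a Metabolic Equivalent of Task (MET) — the activity's energy cost
as a multiple of resting metabolism. A plot's category intensity is

$$\mathrm{EBI} = \sum_i \mathrm{MET}_{EB,i} \, N_{EB,i},$$

likewise LBI and SBI, and the overall index is their sum (the
categories partition the taxonomy, so OBI is additive by construction;
`score_plots()` computes it as the sum so the identity holds to machine
precision). Units are MET·persons. Records from all of a plot's
observation sessions are pooled by default; session-level scores are a
`dplyr::filter()` away, since nothing in the method fixes one choice.
Zero-count records are legal and contribute nothing — they represent
observation sessions without activity.

The packaged MET table follows the 2011 Adult Compendium conventions.
It is a documented stand-in: studies that have activity-specific local
values (e.g. for scooter riding or shuttlecock kicking, which the
compendium does not list) should pass their own table; every function
accepts one, and the package's exact worked examples use explicit
fixture METs so nothing downstream depends on the stand-in values.

Reported percentage shares (participation by subcategory, demographic
strata) are rounded *half-up* to two decimals — commercial rounding, not
R's banker's rounding — because that is the convention the reference
shares were printed with.

## Landscape profiles

Each plot is photographed from at least 9 points in 4 cardinal
directions (≥ 36 images per plot; `photo_protocol_plan()` enumerates
campaigns). A semantic-segmentation model assigns every pixel a scene
class; `remap_labels()` folds those classes onto 11 landscape features,
with everything else counted as `other`, so for any label map the 11
fractions plus `other` sum to exactly 1. The packaged
ADE20K-to-feature remap table is a *reconstruction* from class
semantics (road/sidewalk/path → pavement; earth/sand/rock/dirt-track →
rough or uneven ground — operationalised as non-paved, minimally
modified ground; bench/seat/chair → resting facility; awning/canopy/
tent → shading facility). Unknown class ids go to `other` with a
warning by default; `unknown = "error"` makes ingestion strict. A plot
profile is the arithmetic mean of its images' fraction vectors.
Descriptive statistics (`landscape_stats()`) default to the sample SD
across plots; whether dispersion should be computed across plots or
across photographs is genuinely open, and across-plots matches the
unit of analysis of the regressions.

## Association models

The statistical chain is deliberately plain:

* **Correlation screen.** Spearman rank correlation (average ranks for
  ties) of each feature against each index, two-sided p-values.
  Pearson is available — the reference report is ambiguous between the
  two — and the method used is always recorded in the output; Spearman
  is the default because the methods description names it and because
  intensity scores are heavy-tailed.
* **Collinearity filter.** VIF$_j = 1/(1-R^2_j)$ from regressing
  feature $j$ on the other candidates; features at or above the
  threshold (default 10) are dropped worst-first, recomputing after
  each drop. Whether the original procedure screened once or
  iterated is unstated; stepwise worst-first is the conservative
  choice and is order-invariant for orthogonal designs. Exact
  collinearity (R² numerically 1) yields an infinite VIF and an
  immediate drop.
* **Regression.** OLS with intercept via `stats::lm()`, reporting
  per-term SE/t/p, R², adjusted R² and the overall F-test. P-values are
  two-sided with no multiple-testing correction, matching the source
  procedure — a documented limitation, not an endorsement.

`reference_models()` returns the four published reduced-form equations
(significant terms only) as ready-to-use model objects;
`reference_models_full()` carries the full term sets including
non-significant terms, with estimates and standard errors as printed.
Their t/p values are *not* reproduced: the printed t-value signs are
internally inconsistent with the estimates, so rather than copy
inconsistent diagnostics the full-model objects leave them `NA`. The
bundled intensity summary table also contains one flagged
inconsistency: for park UP-7 the printed category means sum to 432.30
while the printed overall mean is 419.79. The package asserts the
discrepancy (it is not reproducible without the raw records) instead of
silently smoothing it over.

Predictions are the affine form and are not clamped — one reference
intercept is −167.14, so negative predictions are meaningful model
output; `floor_zero = TRUE` truncates when a non-negative surface is
required for presentation.

## Park-wide mapping

Crowdsourced geotagged images are filtered on three rules: short-side
resolution ≥ 1080 px (the source threshold conflates dpi and
resolution; this interpretation is configurable), landscape-related
content, and first occurrence of an exact content hash (near-duplicate
detection is out of scope). The park boundary — a projected-metre
GeoJSON Polygon/MultiPolygon — is tiled with square cells (default
30 m, matching the plot size) from the bounding-box minimum, keeping
cells that intersect the boundary. Inputs that look like geographic
degrees (sub-degree extent within ±180/±90) are rejected with a
message rather than silently reprojected.

Cell membership uses half-open intervals $[x_\min, x_\min + s)$ in both
axes with the outermost upper edges closed — the standard raster
convention, stated explicitly because the source is silent: a point on
a shared edge belongs to the higher-index cell, and every point in the
gridded area belongs to exactly one cell. Cell features are the mean of
member-point features; empty cells carry no-data and are excluded from
prediction and classification (the alternative, interpolation, is
deliberately not offered — it would manufacture landscape data where no
image evidence exists).

Scores are classified with Fisher–Jenks natural breaks: the exact
dynamic-programming partition of the sorted values minimising
within-class sum of squared deviations. Ties between equally optimal
partitions are broken toward the smaller upper class, making the
classification deterministic. The number of classes defaults to 5 — a
conventional choropleth choice; the source never states its k — and the
goodness of variance fit (GVF = 1 − SSD$_w$/SSD$_t$) is reported, 0 for
k = 1 by convention.

## Observer reliability

`icc()` computes single-measure intraclass correlations from the ANOVA
mean squares: one-way ICC(1,1), two-way random absolute-agreement
ICC(2,1), and two-way mixed consistency ICC(3,1). ICC(2,1) is the
default — the standard form for dual-observer SOPARC reliability, where
observers are exchangeable and absolute agreement of counts matters;
the form behind the reference value 0.979 is unstated, so the choice is
documented rather than assumed provable. Percent agreement is the share
of matching paired codes, half-up rounded to one decimal, optionally
stratified. The reference reliability values serve as calibration
targets for the generator, not as re-derivable results.

## The synthetic-data generator

Field data behind the reference study is unreleased, so the generator
reproduces its *statistical structure* under the stated study
conditions, which are the defaults:

* 68 plots allocated to seven parks as in the reference design
  (5/5/5/10/12/15/16);
* per-feature fraction distributions: independent normals at the
  reference overall means and SDs (tree 0.3626 ± 0.11, pavement
  0.1289 ± 0.07, ...), clipped to [0, 1]; profiles summing above 0.95
  are rescaled to 0.95, keeping ≥ 5 % of each scene unmapped as real
  segmentations do. Only marginal moments are published, so
  independence is assumed and documented; the true joint covariance is
  unknowable from the source tables.
* behavior targets: category intensities are
  $\max(0, \text{model prediction} + N(0, \sigma))$ under the packaged
  equations, with default residual SDs derived from the reference
  fits' unexplained variance ($\sigma = \sqrt{1-R^2}\,\mathrm{SD}$:
  137/78/128 MET·persons for EBI/LBI/SBI). Each target is decomposed
  into records by greedily drawing category codes and integer counts
  until the remainder is below the category's smallest MET, so
  realised scores land within one MET unit of the target and OBI
  emerges as the category sum. `exact = TRUE` instead emits one
  fractional-count record per category — an idealised mode whose scores
  match targets to machine precision, used for model-recovery
  experiments where decomposition granularity would otherwise dominate.
* a 320 m × 240 m park (7.68 ha, the mapped reference park's area)
  with points uniform over it, features following a smooth sinusoidal
  spatial field plus N(0, 0.05) noise, and 5 % / 3 % / 2 % of points
  flagged low-resolution / non-landscape / duplicate to exercise the
  filter;
* rating matrices with between-target variance chosen so the
  population ICC equals the requested value.

Every stage draws from its own sub-seed of the configuration seed, so
outputs are bit-reproducible and independent across stages.

What passing tests on this generator establishes: the estimators
recover known truth (OLS coefficients to 1e−6 without noise, nominal
95 % CI coverage with noise, ICC within sampling error of its target),
the pipeline's identities hold (additivity, conservation, partition,
determinism), and the spatial machinery matches brute-force oracles.
What it does not establish: behavior on real parks — real landscape
features co-vary (trees and shade, pavement and facilities), real
behavior is temporally and spatially autocorrelated, and real
crowdsourced imagery is biased toward photogenic locations. None of
those structures are emulated, and conclusions about real-world effect
sizes should not be read from synthetic recoveries. The truncation of
negative intensity targets at zero also means generated scores are not
exactly linear in the features; recovery experiments therefore
generate outcomes directly from the linear form where exactness is the
point.

## Problem sizes and numerical tolerances

The test suite runs the study replica at its native size (68 plots) and
the property suites at sizes where independent oracles are exact:
Jenks against exhaustive partition enumeration at n ≤ 12, k ≤ 4 (200
random instances); CI coverage pooled over all slope terms of 500
replicated fits; scoring additivity over 1,000 random record sets; ICC
recovery at 200 rated targets. Exact worked values are asserted at
1e−9–1e−12; stochastic checks use bounds at least five standard errors
wide of their targets unless a tighter bound is itself the property
under test. Fraction-sum validation tolerates 1e−6 of accumulated
floating-point error on ingestion; Jenks class membership uses a 1e−12
slack when matching values to class maxima.

## Known limitations

* The MET table and the ADE20K remap are reconstructions, clearly
  flagged; both are user-overridable and all exact tests are
  parameterised over explicit fixtures.
* Models are plain OLS on a cross-section of plots: no spatial
  autocorrelation, no mixed effects for parks, no regularisation, and
  no multiple-testing correction. These mirror the reference procedure
  and bound what predictions over a new park mean.
* Geometry is axis-aligned and lightweight by design: boundaries must
  arrive projected in metres; reprojection, kernel smoothing and
  basemap cartography are out of scope.
* Empty fishnet cells stay empty; the maps show where image evidence
  exists, not an interpolated surface.
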