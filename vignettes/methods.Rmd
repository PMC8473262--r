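---
title: "Models and methods behind lakechla"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lakechla}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakechla)
```

`lakechla` chains five analysis stages — chlorophyll-a retrieval from
reflectance spectra, feature and event derivation, diel-pattern clustering,
driver classification, and nonparametric multiplicative regression (NPMR) —
plus a synthetic scenario generator that provides controlled inputs with the
statistical structure the analysis assumes. This vignette explains each
model, its assumptions, the tunable parameters and their defaults, the
numerical choices, and what the package's tests do and do not demonstrate
about real station data.

## Chlorophyll-a retrieval

For turbid, eutrophic waters, Chl-a is retrieved from the red/near-infrared
reflectance ratio:

$$\mathrm{Chl} = \frac{\dfrac{R_{rs}(704)}{R_{rs}(672)}\,(a_w(704) + b_b)
  - a_w(672) - b_b^{\,p}}{a^*}, \qquad
  b_b = \frac{b_1\,R_{rs}(776)}{b_2 - b_3\,R_{rs}(776)}$$

The ratio exploits the Chl-a absorption trough near 672 nm against the
scattering peak near 704 nm; backscattering is estimated where pigment
absorption is negligible (776 nm). Default constants (`aw672 = 0.40`,
`aw704 = 0.70` m⁻¹, `p = 1.06`, `a* = 0.016` m² mg⁻¹, `b1 = 1.61`,
`b2 = 0.082`, `b3 = 0.60`) follow the semi-analytical algorithm family this
model belongs to; they are deliberate *defaults to be replaced by a
site-specific calibration*, and nothing in the package's validation depends
on their absolute values — all round-trip tests use the algebraic forward
model `forward_rrs()`, which inverts the retrieval exactly.

Bands are extracted by linear interpolation between the two bracketing
channels: at the instrument's 4.6 nm channel spacing a nearest-channel rule
can be off by up to 2.3 nm, while interpolation is deterministic and
testable. Quality control never silently deletes data: negative input bands
(`negative_band`), the backscatter pole and non-positive red band
(`denominator`), out-of-window bands (`band_missing`), and negative or
implausible retrievals (`out_of_range`, clipped to zero or value withheld)
are all flagged in place so time-series continuity is preserved and every
exclusion is accountable.

## Feature derivation and event detection

All timestamps are UTC throughout; no daylight-saving arithmetic exists
anywhere in the package. Aggregation bins are half-open `[start, start + Δ)`
labelled by their start; empty bins are absent rather than zero;
concentrations and most weather variables are averaged while precipitation
is summed and wind direction is vector-averaged.

Antecedent features use the **7 days strictly before** the index day —
"antecedent" is read literally so the features can serve as lagged
predictors — and a window with any missing day yields a missing value
rather than a mean over fewer days (the conservative reading; partial-window
means would silently change the estimator near gaps). Wind vectors use the
meteorological from-direction convention, `u = −speed·sin(dir)`,
`v = −speed·cos(dir)`, so a westerly wind has positive `u`. Stations that
report only daily values are broadcast to the 24 hours of their day (flagged
`broadcast`) when hourly resolution is required.

Storm-end cooling is quantified by `detect_max_decline()`: the (peak,
trough) day pair maximizing the temperature drop with the trough at most
`window_days` (default 3) after the peak, ties resolved to the earliest
peak. Three days covers the 1–3-day spans over which the 2019 heatwave
terminated at the three study sites while excluding slow seasonal decline.

The diel window is the 8 inclusive hourly bins 09:00–16:00 UTC, and each
day's bins are divided by that day's window maximum, so profiles encode
*pattern*, not concentration; a complete profile has maximum exactly 1.
Multi-site comparisons first pass through `common_days()`, which keeps only
dates where every site has a complete profile — an unbalanced panel would
otherwise let one site's gaps tilt the cluster composition.

## Diel clustering

Distances between relativized profiles are quantitative Sørensen
(Bray–Curtis), $d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$, bounded
in [0, 1] on nonnegative data (computed via `vegan::vegdist`; a pair of
all-zero profiles has no defined distance and is reported as an error naming
the rows). Agglomeration uses the Lance–Williams update

$$d(k,\ i \cup j) = \alpha\,[d(k,i) + d(k,j)] + \beta\, d(i,j),
  \qquad \alpha = (1-\beta)/2$$

with β = −0.25, the conventional "flexible" setting in ecological
classification; β = 0 recovers WPGMA, and the tests verify both that
reduction and agreement with `cluster::agnes(method = "flexible")` and with
a brute-force oracle. Ties in the minimum-distance pair are broken by the
lexicographically smallest pair of cluster ids, making the tree
deterministic. Merge heights are reported exactly as computed — flexible
beta can invert (a later merge below an earlier one), so monotonicity is
*not* asserted and no dendrogram "repair" is applied.

Cutting undoes the last k − 1 merges. The number of end groups k is a user
choice: no automatic pruning criterion is defended here, because none can be
attributed to the analysis this package reproduces. Groups are numbered by
the 1-based original row index (chronological by date, then site
alphabetically) of their first member — which is why a five-group solution
carries labels like 1, 2, 6, 8, 85 rather than 1…5. The numbering is purely
nominal but makes assignments reproducible and comparable across runs.

## Driver classification

Before classification, collinear predictors are screened: among numeric
candidates, the highest-|r| pair with |r| ≥ 0.6 loses its member with the
larger mean absolute correlation to all others (ties: the later column),
iterating until no pair exceeds the threshold. The categorical site factor
never enters the correlation and is always retained.

Cluster membership is then modelled by multinomial logistic regression,
fitted by Newton iterations on the softmax log-likelihood with step halving
(the likelihood trace is non-decreasing by construction) from a zero start,
so the fit is deterministic. Predictors are z-scored internally for
conditioning; coefficients and their covariance are mapped back to the
original scale exactly (the transform is linear in coefficient space). The
reference class is the lowest group number. Standard errors come from the
inverse observed information; when that matrix is near-singular — likely
with clusters of ten-odd days, where quasi-separation is common — the fit
is repeated with a tiny ridge (L2 = 10⁻⁶) and flagged. Wald z = estimate/SE
with two-tailed normal p-values.

Evaluation is deliberately resubstitution, not cross-validation: with some
clusters holding very few days, a held-out split would be dominated by
partition noise. The confusion table therefore measures *reclassification*
ability only; its columns (true clusters) are normalized to sum to 100, with
per-cluster percent correct on the diagonal. Binary reduction to
`glm(binomial)` and multi-class agreement with `nnet::multinom` are enforced
in the test suite as independent cross-checks.

## NPMR

The estimate at a point x is a local mean with multiplicative Gaussian
kernels,

$$\hat y(x) = \frac{\sum_j w_j y_j}{\sum_j w_j}, \qquad
  w_j = \prod_k \exp\!\left(-\tfrac12 \left(\frac{x_k - x_{jk}}{t_k}\right)^2\right)$$

where the tolerance $t_k$ is the kernel SD in predictor k's units.
Multiplying rather than adding kernel weights lets predictors interact
without fixed coefficients — a point is a neighbor only if it is close in
*every* predictor. Fit is the leave-one-out cross-validated
$xR^2 = 1 - \sum_i (y_i - \hat y_{-i})^2 / \sum_i (y_i - \bar y)^2$, which
can be negative; the effective local sample size is the neighborhood
$N^*_i = \sum_{j \ne i} w_{ij}$, and its mean is reported beside xR².

Choices the reference implementations of this method do not document are
exposed as configuration, with these defaults:

* **Tolerance grid**: fractions {0.025, 0.05, 0.10, 0.15, 0.20, 0.30, 0.45,
  0.65, 1.0} of each predictor's observed range — wide enough to span
  near-interpolation through near-flat kernels.
* **Minimum neighborhood**: a point gets no estimate if its total
  leave-one-out weight is below `0.05 n`; such points are excluded from both
  xR² sums and counted. (The three-point worked example in the documentation
  sets this to 0, since its endpoint neighborhoods are necessarily tiny.)
* **Coverage**: during tolerance optimization a combination is admissible
  only if at least 90% of points receive estimates. Without this rule the
  search can inflate xR² arbitrarily by shrinking tolerances until only a
  handful of mutually close points remain — a failure mode observed directly
  during development.
* **Stopping rule**: forward selection stops when the best next predictor
  improves xR² by less than 0.02; gains of the order of one percentage point
  are treated as interchangeable alternatives, not improvements.
* **Tolerance optimization**: exhaustive over the Cartesian grid while the
  combination count is ≤ 2000 (which makes the small-grid equivalence with
  an enumeration oracle exact), coordinate-descent passes beyond that.

Sensitivity of predictor k nudges every observation by ±5% of that
predictor's range and scales the mean absolute deviation of the estimate by
the response range and the nudge fraction; a linear response at
near-interpolation tolerance calibrates to ≈ 1, and a predictor outside the
model scores 0. Nudges are applied at the data points (not on a prediction
grid), keeping the measure tied to the observed design.

Significance uses a response-permutation test: y is permuted, tolerances are
re-optimized for the fixed predictor set, and
$p = (1 + \#\{xR^2_{perm} \ge xR^2_{obs}\})/(1 + n_{perm})$ with 199
permutations by default (resolving p < 0.05 at minimal cost). Because the
weight matrices do not depend on y, the per-permutation grid search reuses
cached kernels and is cheap. Re-optimizing under permutation matters: it
subjects the null replicates to the same selection optimism as the observed
fit. Leave-one-out excludes only the estimation point itself; no temporal
blocking is applied even though daily series are autocorrelated — matching
the method as cited — so xR² on strongly autocorrelated responses should be
read as in-sample-adjacent skill, and blocked variants are a possible
extension, not a default.

## The synthetic scenario generator

`scenario_config()` defaults encode the study window the analysis targets:
three sites with contrasting climates (Mediterranean and humid continental),
1 July–30 September 2019 at 15-minute cadence, a week-long heatwave
(21–27 July, +8 °C) terminated by a storm on 28 July with a 19.8 °C
day-over-day temperature drop, a wind peak of 12 m s⁻¹, 30 mm of rain, and
a two-fold post-storm Chl-a step. The step magnitude is a free scenario
parameter — the narrative it emulates reports a marked, persistent increase
but no number. Per-site streams use independent sub-seeds, so adding a site
never perturbs another site's data.

Temperature is a seasonal sinusoid plus a 4 °C diurnal cycle, the heatwave
block, the storm deficit and AR(1) noise; the storm-day offset is solved so
the realized day-over-day decline of the daily mean equals `temp_drop`
exactly at zero noise, which is what makes the event-detection construction
test exact. Daily Chl-a follows a configurable response surface — the
default is a Gaussian seasonal peak (early September) times log-linear
temperature and wind effects — under mean-one lognormal noise
(`noise_cv = 0.1`), chosen because concentrations are positive and
right-skewed. Within-day shape is drawn per day from a per-site mixture of
*concave* (midday dip), *convex* (midday peak) and *flat*; the dip/peak
depth is `d0 + d1·irradiance − d2·wind` clipped to [0, 0.8], encoding the
quenching-like association of midday dips with bright, calm days as a
testable generative rule.

Reflectance spectra are produced by the exact forward model at the three
signal bands on the instrument's 4.6 nm ladder *augmented with exactly
672/704/776 nm*, so that noiseless spectra retrieve the generating
concentration to machine precision; the rest of the spectrum is a smooth
spline through fixed anchor reflectances and intentionally carries no
signal. The generator therefore emulates the statistical structure the
pipeline assumes — not radiative transfer, not cyanobacteria scum optics,
not hydrology. Passing recovery tests show the *estimators* work under
known truth; they cannot certify the retrieval constants, the absence of
instrument artefacts, or weather–Chl-a mechanisms in real lakes.

## Problem sizes and determinism

Tests and the acceptance script run at desk scale: 60–92 site-days per
scenario, 80 planted diel profiles, 20 replicates for sensitivity ranking,
150 null replicates (600 Wald tests) and 100 permutation meta-replicates
(99 permutations each). Brute-force oracles cover the kernel estimator
(n ≤ 50, p ≤ 3, agreement to 10⁻¹²), agglomeration (n ≤ 6), the stepwise
search (2 candidates × 5-point grid, exhaustive enumeration) and event
detection. Every stochastic component takes an explicit seed; pipeline
reruns with the same configuration are byte-identical.

## Known limitations

* The retrieval constants are documented defaults, not a calibration; users
  with match-up data should refit them and can validate with
  `matchup_stats()`.
* The two-viewing-geometry merge performed on the physical instrument is out
  of scope; spectra are taken as delivered.
* k for the cluster cut is user-set; no gap statistic or pruning rule is
  provided.
* NPMR leave-one-out ignores temporal autocorrelation (see above).
* The generator's weather is structurally simple (AR(1) noise, clear-sky
  irradiance with rain-coupled clouds); it is a test harness, not a weather
  model.
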