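# lakechla

High-frequency chlorophyll-a monitoring analysis for shallow, eutrophic
lakes and lagoons observed by fixed-station hyperspectral radiometers.

Autonomous spectroradiometer stations measure remote-sensing reflectance
Rrs(λ) over 350–900 nm every ~15 minutes. From those spectra a chlorophyll-a
(Chl-a) time series can be derived and confronted with local weather to ask
two questions that matter for lake management under a warming climate: what
shapes the *within-day* (diel) Chl-a pattern, and how do weather events —
notably mid-summer heatwaves and the storms that end them — restructure the
*seasonal* Chl-a trajectory? `lakechla` implements that full analysis
chain for ecologists and remote-sensing scientists, together with a
synthetic multi-site scenario generator so every stage is testable without
access to station data.

## What the package computes

**Chl-a retrieval** (turbid/eutrophic water, red/NIR band ratio):

    Chl = [ (Rrs(704)/Rrs(672)) · (aw(704) + bb) − aw(672) − bb^p ] / a*
    bb  = b1 · Rrs(776) / (b2 − b3 · Rrs(776))

with pure-water absorptions `aw`, particulate backscattering `bb` estimated
at 776 nm, and Chl-a specific absorption `a*`. An exact algebraic forward
model (`forward_rrs()`) supports round-trip validation.

**Diel pattern analysis**: hourly Chl-a 09:00–16:00 UTC, relativized to each
day's maximum, clustered with quantitative Sørensen (Bray–Curtis) distance
d(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ) and flexible-beta linkage (Lance–Williams,
α = (1−β)/2, β = −0.25), end groups numbered by the row of their first
member. A multinomial logistic model with two-tailed Wald z tests then asks
whether wind, irradiance, temperature and site can classify the diel groups
(resubstitution confusion table, columns normalized to 100%).

**Event and feature derivation**: daily means, 7-day strictly-antecedent
rain totals and wind/temperature means, meteorological wind vectors
(u = −speed·sin dir, v = −speed·cos dir), and the largest short-window
temperature decline per site (the storm-end signature).

**NPMR** — Nonparametric Multiplicative Regression, written from scratch: a
local-mean estimator with multiplicative Gaussian kernels
w(i,j) = Πₖ exp(−½((xᵢₖ−xⱼₖ)/tₖ)²), leave-one-out cross-validated R²
(xR², can be negative), average neighborhood size N*, stepwise free search
over predictors and tolerance grids, ±5%-of-range sensitivity analysis, and
a response-permutation significance test.

## Worked example

```r
library(lakechla)

cfg <- scenario_config(seed = 42)   # 3 sites, 1 Jul–30 Sep 2019, storm 28 Jul
w   <- generate_weather(cfg)
ct  <- generate_chla_truth(cfg, w)

## diel clustering at k = 5
prof <- common_days(diel_profiles(aggregate_series(ct$obs, "hourly")))
asg  <- cut_to_groups(flexible_beta_cluster(sorensen_matrix(prof)), 5)
table(asg$group)
#>  1  2  6  8 85
#> 72 61 49 60 34

## storm-end temperature drop per site
feats <- do.call(rbind, lapply(names(w), function(s)
  as.data.frame(antecedent_features(w[[s]], aggregate_series(ct$obs, "daily")))))
detect_max_decline(feats[, c("site", "date", "temp")])
#>        site  peak_date peak_temp trough_date trough_temp  decline
#> 1  curonian 2019-07-26  33.44948  2019-07-28    13.26787 20.18161
#> 2 trasimeno 2019-07-27  38.70485  2019-07-28    19.08536 19.61949
#> 3 vortsjarv 2019-07-25  31.15422  2019-07-28    10.93648 20.21774

## NPMR of daily Chl-a on weather
d <- feats[feats$site == "trasimeno", ]
free_search(d, "chla_daily", c("doy", "temp", "temp7", "wind", "rain7"))
#> <npmr_search> best model per size (xR2): 1: 0.891
#> <npmr_model> chla_daily ~ doy; n = 85 (85 estimated)
#>   xR2 = 0.8914, average neighborhood N* = 9.11
#>   tolerances: doy = 4.2
```

The cluster labels (1, 2, 6, 8, 85) are first-member row numbers, not
sequential ids. Day of year dominates the seasonal model — adding weather
predictors on top of it yields gains below the 0.02 xR² acceptance
threshold in this scenario — and the detected declines sit at the
configured ~19.8 °C storm drop plus sampling noise.

A YAML-driven end-to-end run (`run_pipeline()`, or the `inst/scripts/lakechla`
command-line wrapper with subcommands `simulate`, `retrieve`, `features`,
`cluster`, `drivers`, `npmr`, `run-all`) writes each stage's tables and a log
under the configured output directory.

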