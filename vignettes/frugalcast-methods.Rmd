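---
title: "Forecasting high/low crop production from climate-variability indices: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting high/low crop production from climate-variability indices: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frugalcast)
```

## The problem

Large-scale modes of climate variability — ENSO (through the Southern
Oscillation Index), the North Atlantic Oscillation, the East Atlantic,
East Atlantic/Western Russia and Scandinavian patterns — modulate European
weather months ahead of the crop season. `frugalcast` asks a deliberately
coarse question: months before harvest, will a region's annual production
be *above* or *below* its (detrended) long-term mean? The answer is a
binary forecast per region and lead time, produced by a fast-and-frugal
decision tree (FFT) over 3-month means of the five indices, validated out
of sample, and tested for significance both per region and across the
whole map of regions.

The package is organised as a pipeline: lead-time features → production
gap-filling and binarization → FFT learning (ifan) → train/test
validation with bootstrap and field significance. Each stage is an
exported function; the `analysis/` scripts chain them on synthetic data.

## Lead-time features

Forecast lead is anchored to a September harvest: lead `k` uses the
3-month window ending `k` months before September, so lead 6 averages
January–March and lead 1 June–August. All windows sit inside one calendar
year; no cross-year windows are formed. `compute_lead_features()` takes
the plain arithmetic mean of the three monthly values per index; a year
enters the feature table only when all three months exist for *every*
index. Missing months drop the year (with a message) rather than being
interpolated — with series this short, imputation would manufacture
predictor information the data do not contain.

Two consequences matter for interpretation. First, adjacent leads share
two of their three months, so their features are strongly correlated and
a genuine signal at one lead usually bleeds into its neighbours; the
per-lead results are not independent tests. Second, the features inherit
whatever standardization the input indices carry; the package uses the
values as given.

## Production gap-filling and the high/low indicator

Regional production records (1000 t fresh weight) are compared, per
country and year, against the national total. With `gap` the national
total minus the sum of non-missing regional records:

* `gap > 0`: each missing region `i` receives
  `gap × HA_i / Σ HA_missing`, where `HA` is its static harvest area —
  the gap is allocated *proportionally to harvest area* among the
  missing regions, so the filled year conserves the national total
  exactly;
* `gap = 0` (to a relative tolerance of 1e-9): missing regions are set
  to zero — the nation saw no unaccounted production;
* `gap < 0`: the regional records are internally inconsistent with the
  national total and the missing values are left missing rather than
  invented.

The proportional rule assumes production scales with harvested area. It
is exact only when a single region is missing (then the gap *is* that
region's production); with several missing regions it distributes the
right total with approximate shares. `fill_production()` records a
provenance flag per cell (`observed`, `filled`, `zero-filled`,
`left-missing`) so downstream users can see which labels rest on
reconstructed values.

Each region's series is then reduced to anomalies: an OLS line of
production on year is removed when its slope is significant at p ≤ 0.1
(two-sided t-test), otherwise the multiyear mean is subtracted. Negative
anomalies are labelled `low`, others `high`. An exactly zero anomaly is
labelled `high`: the definition uses strict inequalities, a rule must
exist, and exact zeros have measure zero on continuous data. Regions with
20 or fewer labelled years are excluded ("longer than 20 years" read
strictly), as are degenerate series whose anomalies are numerically zero
(relative tolerance 1e-8) — a perfectly linear series carries no
classifiable variability. Filled values take part in the trend fit; their
provenance flags preserve the audit trail.

## The fast-and-frugal tree and the ifan construction

An FFT is a depth-at-most-five decision list: each non-final node tests
one cue against a threshold and *exits* with a classification on one
side; the final node classifies both sides. Once a case exits, later
cues cannot change the decision (non-compensatory). Construction follows
the ifan algorithm:

1. **Threshold each cue.** Candidate thresholds are the midpoints
   between consecutive sorted distinct training values — an exhaustive
   sweep over decision-equivalent cuts, deterministic by construction.
   Both directions (`≤` low, `>` low) are scored by standalone balanced
   accuracy, `BACC = (HR + CR)/2`, with `HR` the fraction of low years
   classified low and `CR` of high years classified high. Ties prefer
   the smaller threshold, then direction `≤`. A constant cue gets its
   single value as threshold and BACC 0.5.
2. **Rank cues** by standalone BACC, descending; ties keep the order in
   which features appear in the table (for the standard feature set:
   `soi, nao, ea, eawr, sca`). The top `max_levels` (≤ 5) cues are
   retained.
3. **Enumerate the fan.** For `k` retained cues, all `2^(k-1)`
   single-exit assignments of the non-final nodes (final node exits
   both ways) form the fan of candidate trees, sharing order and
   thresholds.
4. **Select** the fan member with the highest training BACC; ties go to
   fewer *effective* levels (the deepest node that actually decides any
   training case), then fan order.

Everything here is deterministic: rerunning a fit on the same data gives
bit-identical trees. Note one subtlety of the fan definition: every fan
member carries all `k` cues, so even when the first cue separates the
training data perfectly, the rows it passes through are decided by the
remaining cues — the fan does not automatically contain the pure
one-cue tree (set `max_levels = 1` for that). The ifan ranking treats
cues independently; correlated predictors are handled greedily, not
jointly.

## ROC and AUC from the fan

The fan members range from exiting `high` everywhere (conservative: low
FAR, low HR) to exiting `low` everywhere (liberal), so their
`(FAR, HR)` points sweep an ROC curve — the only multi-point curve a
single FFT method produces. `fan_auc()` augments the points with the
`(0,0)` and `(1,1)` anchors, sorts by FAR then HR, removes duplicates,
and integrates by the trapezoidal rule. A fan containing a perfect
classifier scores exactly 1.0; label-independent predictions average
0.5. AUC is computed on the held-out test years by default — the
quantity of interest is hindcast skill on unseen years, not training
fit.

## The validation recipe

Per region and lead:

1. **Split** the labelled years 70/30, stratified by label with
   largest-remainder allocation so both classes appear on both sides
   whenever possible (an unstratified split of a 39-year series would
   otherwise occasionally strand a class and leave BACC undefined).
   Splits are seeded and reproducible.
2. **Pruning.** For each candidate tree size 1–5, fit the fan on the
   training years and score the selected tree's BACC on the test years;
   keep the size with the highest test BACC, ties to the smaller tree.
   Because this picks the maximum of five correlated draws, the
   *selected* test BACC is optimistically biased under the null (about
   0.57 rather than 0.50 in simulation) — the per-level values, which
   `select_pruning()` also returns, are the calibrated ones. The
   bootstrap below is what turns the selected skill into a calibrated
   p-value.
3. **AUC** of the fan at the selected size, on the test years.
4. **Bootstrap significance.** The null resamples the label vector with
   replacement (severing the climate–production link while keeping
   features, the train/test partition, and the selected pruning fixed),
   refits the fan and recomputes test AUC; `p = (1 + #{AUC_null ≥
   AUC_obs}) / (n_iter + 1)` over 1000 iterations by default. Holding
   the partition and pruning fixed keeps the null cheap; simulation at
   the study conditions shows the resulting test has type-I rate ≈ 0.10
   at the nominal 0.1 level. A permutation null (resampling without
   replacement, preserving class counts exactly) is available via
   `null_method = "permutation"`. Degenerate resamples that strand a
   class are redrawn, with a retry cap.
5. **Statistics.** HR, CR, FAR = 1−CR, MS = 1−HR, PPV = HR/(HR+FAR),
   NPV = CR/(CR+MS) and BACC of the selected tree on the test years.

A region-lead is *significant* when test AUC > 0.7 **and** p < 0.1.
Finally the train and test years are recombined and the fan refitted at
the selected size; that tree — its cues, order, directions and
thresholds — is the reportable model. Across regions, field
significance per lead is the exact upper binomial tail
`P(X ≥ n_significant)` with `X ~ Binomial(n_tests, 0.1)`: it asks
whether the count of locally significant regions exceeds what 10%
false-positive chance would produce. No further multiple-testing
correction is applied across the six leads; as noted above they are
correlated, and the binomial null also ignores spatial correlation
between regions — both make the field test anti-conservative on real
maps, which is a known limitation.

## The synthetic generator

`scenario_config()` fixes the study conditions the tests and analysis
scripts run under:

| parameter | default | why |
|---|---|---|
| `n_years` | 39 | the 1975–2013 span of the feature years |
| `n_regions` | 20 | a desk-scale map; calibration runs use 100–200 |
| `ar1_rho` | 0.3 | monthly teleconnection indices are weakly red |
| `driving_index`, `driving_lead` | NAO, 3 | one planted driver at a mid-range lead |
| `effect_size` | 4 | "strong signal": 4 noise SDs of class separation, so the label agrees with the driver ≈ 98% of years |
| `trend_slope` | 0.5 (1000 t/yr) | a mild technological trend |
| `noise_sd` | 10 (1000 t) | year-to-year variability unrelated to the driver |
| `missing_rate` | 0.1 | EUROSTAT-style patchiness |

Indices are independent AR(1) series standardized over the panel. The
production link is a step: a positive 3-month mean of the driving index
*lowers* production by `effect_size × noise_sd / 2`, a non-positive one
raises it equally — a threshold mechanism for which an FFT is the
correctly specified model class (a `linear` link exists for
misspecification studies). Harvest areas are static and production
bases scale with them, so proportional gap-filling is coherent; national
series are exact sums of the pre-blanking truth, making single-missing
gap-filling exactly recoverable. The null scenario is `effect_size = 0`.

What the generator does *not* emulate: cross-correlated indices (real
teleconnections overlap; independence matches ifan's assumption and
makes recovery tests unambiguous), spatially correlated region noise,
reporting errors and revisions, or non-linear trends. Passing tests
therefore demonstrate that the machinery is correct and calibrated under
its own assumptions — not that real crop data carry this much
predictability.

## Numerical choices and problem sizes

All tie-breaks (threshold, direction, cue order, tree selection, fan
order) are deterministic, so the only randomness is in seeded splits,
bootstraps and the generator; every seed is derived from named master
seeds by a fixed hash of the (region, lead) tag, which makes results
independent of evaluation order. Gap tolerance is relative 1e-9;
degenerate-anomaly tolerance relative 1e-8. The test suite exercises the
calibration claims at 200 null regions with 200 bootstrap iterations and
signal recovery at 100 regions, and verifies the cue-threshold search
against exhaustive brute force on 500 small datasets and the AUC against
an independent trapezoid on random fans; the demo analysis runs 20
regions × 6 leads at 200 bootstrap iterations. These sizes are the
package's documented study conditions for its own claims.
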