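---
title: "Methods: multi-criteria grassland assessment and zoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-criteria grassland assessment and zoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind each stage of the
pipeline, the assumptions the stages make, the parameters a user may want to
touch, and the numerical and design decisions taken where more than one
defensible convention exists.

## The three criteria

### Grassland quality (plot → landscape → region)

**Plot scale.** Quality is scored from 14 vegetation and soil indicators.
Each indicator is oriented so that larger means better (bulk density is
negated; pH is first mapped to its distance from neutral, |pH − 7|, and then
negated) and min-max standardized to [0, 1], with the (min, max) pair stored
so the same affine map can be replayed on new data. Min-max rather than
z-score standardization is the default because the index is meant to live on
a bounded, interpretable [0, 1] scale; a z-score option exists for
sensitivity analyses but forfeits the bounds.

Indicator selection and weighting use PCA. Two conventions are bundled
deliberately: the eigenvalue-greater-than-one (Kaiser) rule for retaining
components, and an absolute-loading cutoff of 0.5 for selecting indicators.
Both are the most common published defaults, and both are only meaningful on
a *correlation-matrix* PCA — eigenvalues of a covariance PCA of min-max data
never approach 1 — so the PCA internally rescales each standardized column
to unit variance, and "loadings" are component correlations (eigenvector ×
component standard deviation). The weight of a selected indicator is
proportional to the sum over retained components of (component variance
fraction × |loading|), normalized to sum to one. This keeps weights
nonnegative and convex, so the resulting GQI = Σ wᵢ·xᵢ is guaranteed to stay
in [0, 1], is invariant to column order, and is monotone in every
positively-oriented indicator. Both thresholds (`eigen_threshold = 1`,
`loading_threshold = 0.5`) are arguments. Alpine meadow and alpine steppe
plots are pooled for weight estimation by default — the per-type sample
sizes (tens of plots) are small for separate PCAs — but nothing prevents
calling the weighting per type.

**Landscape scale.** The plot GQI is regressed on candidate vegetation
indices computed from five-band (B, G, R, RE, NIR) UAV scenes. The package
ships a registry of 37 canonical indices with their formulas as both code
and documentation strings; the candidate set is user-extensible, because no
fixed list of indices is canonical across sensors. Selection is
bidirectional stepwise search from the empty model under AIC
(`n·log(RSS/n) + 2p`, the `stats::step()` convention), with two
deterministic details worth stating:

* ties are broken by preferring deletions, then lexicographic variable
  name, so the search is reproducible across platforms;
* the RSS is floored at 10⁻¹⁰ × SST. Without the floor, an exactly
  collinear response (an artificial but testable case) lets AIC "improve"
  indefinitely through sub-epsilon residual shrinkage.

The stepwise survivors are then refined by a 500-tree random forest:
permutation importance (mean training-MSE increase over 10 fixed-seed
shuffles per variable), retaining variables above the mean importance and
never emptying the set (the single top variable is kept if all fall below
the mean). The final landscape predictor is the OLS refit on the retained
set — the forest ranks, the linear model predicts — because a transferable
regression equation, not a black-box ensemble, is the product handed to the
next scale. Validation holds out 30% of plots, stratified by grassland type
(per-type training counts are `round(0.7 · n_type)`, giving 53–54 training
plots out of 77), and reports R² on both folds; the entire builder runs
inside the training fold only.

Stepwise-AIC is known to admit noise variables at a per-candidate rate of
roughly 16% (a variable enters when its partial t² exceeds ≈ 2), so with
~30 candidates the stepwise set alone typically carries several spurious
indices even for a pure-noise response; the permutation-importance
refinement is the stage that actually prunes them. The test suite measures
both behaviours explicitly rather than pretending stepwise alone is clean.

**Regional scale.** The landscape GQI is paired with satellite NDVI, EVI and
LAI and fitted by PLS1 (NIPALS on centered/scaled predictors, coefficients
back-transformed). With only three predictors the component count is capped
at 3; it is chosen by leave-one-out cross-validation, minimizing the LOOCV
RMSE and reporting R²cv = 1 − PRESS/SST. With all three components PLS1
reproduces OLS exactly, which the tests exploit as an oracle. Training
pairs match support by pairing each plot's landscape-GQI prediction with
the regional predictor values at the plot's pixel; on real data with a
coarse satellite grid the defensible analogue is scene-mean pairing, and
the pairing is deliberately kept outside the fitting function so either can
be supplied. Predictions are made only where the type mask is AM or AS,
clipped to [0, 1] (the GQI is defined on that scale; the clipped fraction
is logged in the model JSON).

### Resilience

Per pixel, the monthly growing-season series are fitted by OLS:

> LAI_t = a·tem_t + b·pre_t + c·LAI_(t−1) + k

`k` sits where an intercept sits and is implemented as the OLS intercept.
Seasons run May–September; by default a month is paired with its
predecessor only *within* a growing season (June–September), because the
month preceding May is eight calendar months away and the lag coefficient
would otherwise mix monthly memory with over-winter persistence. A naive
lag rule is available. Pixels need at least 30 usable pairs (with 20 years
× 5 months there are 80); fewer pairs, or a singular design, give nodata
with a reason code rather than a silent value.

Fitted a, b, c are min-max normalized to [0, 1] *within each grassland
type* — meadow and steppe are ecologically distinct populations and their
downstream classifications are per-type, so mixing them in one
normalization would let one type's range distort the other's index. Then
RI = 1 − c_norm, and SI = a_norm·sens(tem) + b_norm·sens(pre), where the
raw sensitivity to a climate variable is 1 minus the residual-variance
ratio of the simple LAI-on-that-variable fit (its R², equal to the squared
Pearson correlation), min-max scaled per type. Normalized rather than raw
a, b enter SI: the coefficients carry units (LAI per °C, LAI per mm) and an
unnormalized SI would be dominated by whichever unit happens to be larger.
Series are used as-is (no detrending or deseasonalization) by default.

### Pressure

Grazing intensity (sheep units km⁻²), growing-season mean temperature and
precipitation are min-max standardized per grassland type and combined as
a weighted mean, equal weights by default. All directions default to +1 —
a literal reading in which larger values mean more pressure — because
silently deciding that, say, low precipitation is the real stressor would
bake an ecological judgement into a default; `pressure_preset_drought()`
documents the (+1, +1, −1) alternative for users who want precipitation to
relieve pressure.

## Classification and zoning

Each criterion surface is classified into three classes by Fisher–Jenks
natural breaks: the exact dynamic program minimizing within-class sum of
squares, run on the per-type population of pixels (the per-type
classification downstream makes joint breaks inconsistent). Inputs above
10,000 values are reduced to a deterministic fixed-seed sample for the DP
and tagged "sampled"; the exact DP's cost is quadratic in n and the
thresholds stabilize well below that size. Goodness of variance fit
(1 − SSW/SST) is reported with every break set. Class intervals are closed
on the right of each break — x ≤ t₁ is low, t₁ < x ≤ t₂ moderate, x > t₂
high — a convention that must simply be fixed once for reproducibility.

The overlay maps the 27 possible (quality, resilience, pressure) label
triples onto five zones: low quality → LQZ regardless of the rest; moderate
quality splits on resilience (high resilience → QRPZ, otherwise QILZ); high
quality splits on pressure (low → HQSZ, otherwise HQPZ). The rule table is
total — the tests enumerate all 27 combinations — so every pixel classified
in all three criteria receives exactly one zone, and per-type zone
fractions sum to 100%.

## The synthetic-data generator

The generator produces every pipeline input from known ground truth, using
the weakest structure each stage assumes, so that tests verify the
*procedures* rather than an invented ecology:

* a latent quality field in [0, 1]: low-pass-filtered Gaussian noise
  (filter scale ≈ grid/8), giving the spatial autocorrelation a regional
  survey would see;
* 77 plots by default, stratified 49 meadow / 28 steppe; the ten
  key-indicator proxies are monotone affine in local quality plus Gaussian
  noise (`noise_sd_indicator = 0.05` on the quality scale — a few percent
  of the field's range, a realistic field-measurement error); available
  N/P, bulk density and pH carry only weak loadings, with intrinsic scatter
  scaled by the same noise knob so the zero-noise configuration is exactly
  deterministic and the full pipeline then recovers the quality ranking
  exactly;
* five-band scenes whose NIR rises and red falls with quality such that
  NIR + R is constant — making NDVI exactly linear in quality before noise,
  the cleanest monotone link a VI regression can hope for;
* a climate cube generated by literally iterating the lagged recursion
  (24-step burn-in discarded, initialized at the deterministic fixed point
  k/(1 − c); the configured c-range must stay below 1 for stationarity),
  with temperature and precipitation as mildly autocorrelated AR(1) series;
* regional NDVI/EVI monotone in quality; regional LAI is the cube's
  temporal mean, i.e. deliberately *not* tied to quality, so the PLSR must
  cope with an uninformative predictor;
* a smooth west-east grazing gradient; the ground-truth pressure field is
  computed from the noise-free layers with the very pressure functions used
  downstream, so the zero-noise round trip is exact by construction.

What the generator does **not** emulate: radiative-transfer physics,
georeferencing, sensor calibration drift, spatially correlated measurement
error, missing data, or the support mismatch between centimetre UAV pixels
and 500-m satellite pixels. Green tests therefore demonstrate that the
procedures are implemented correctly and recover known structure under
realistic noise — not that the pipeline is robust to every pathology of
real field campaigns.

## Problem sizes and numerical tolerances

The validation suite uses: 500 pixels × 100 months for coefficient
recovery (chosen to estimate the lag coefficient to a few hundredths);
50 random arrays of length ≤ 25 for the natural-breaks oracle (exhaustive
enumeration is exact there); 20 random small datasets for the PLSR = OLS
and LOOCV oracles at 10⁻⁸; 50 seeds of 77 × 30 index tables for selection
rates; and the default 60 × 80 grid for the end-to-end run. Exact linear
identities are asserted at 10⁻⁸–10⁻¹²; Monte-Carlo rates at the fractions
stated in the tests.

Degenerate inputs fail loudly and early: constant indicator columns,
constant coefficient fields, all-constant predictor sets, too-few lag
pairs, footprints outside rasters, and grid mismatches all raise errors
naming the offending object, and per-pixel failures carry reason codes
instead of NAs of unknown origin.

## Known limitations

* The stepwise stage inherits AIC's liberal inclusion behaviour (see
  above); interpret the stepwise set as candidates, the refined set as the
  selection.
* Jenks breaks on the "sampled" path are only as stable as a 10,000-value
  sample; for borderline class boundaries the GVF and thresholds should be
  inspected.
* The regional model is linear in three predictors; strongly nonlinear
  quality–reflectance relations would need a richer predictor set upstream
  of the PLSR, not a different fitter.
* Per-type min-max normalizations make RI, SI and pressure *relative within
  a grassland type and study area*: values are not comparable across
  studies, only classes and zones are.
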