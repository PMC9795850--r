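---
title: "Methods: plot-level yield-parameter estimation from UAV RGB imagery"
author: "uavyield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plot-level yield-parameter estimation from UAV RGB imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Breeding trials with many hundreds of cultivars score *yield parameters*
per plot — grain number of seeds per plant and grain weight per plant —
because plot yield itself is too sensitive to chance factors in small
two-row plots. `uavyield` implements a complete analysis chain that
estimates these two quantities from multi-date UAV RGB orthomosaics and
photogrammetric digital surface models (DSMs), under lodging (ordinal
severity 1 = all plants upright to 5 = all lodged, which depresses
yield):

1. **Plot clipping** (`clipPlot`) — pixel-centre, half-open windows cut
   each plot rectangle out of the registered rasters.
2. **Vegetation block** (`plotVIFeatures`) — 24 features: 15 named
   visible-band indices (CIVE, COMB1, COMB2, ExG, EXGR, GRI, GRVI,
   MGRVI, PPRb, RGBVI, SAVI, VARI, VDVI, VEG, WI), the six normalized
   bands (Rn, Gn, Bn and the chromatic coordinates r, g, b) and the
   three raw band means.
3. **Canopy cover** (`canopyCover`) — the excess green index
   `EGI = (2G - R - B)/G`, thresholded at 0.05.
4. **Crop height** (`estimateBareDEM`, `computeCHM`, `plotHeight`) — a
   per-plot bare-ground elevation from the pre-emergence flight (Otsu
   split, lower-class mean), pixel-wise `CHM = DSM - DEM` with negatives
   clipped to zero, aggregated as the canopy-masked mean.
5. **Texture block** (`plotTextureFeatures`) — gray-level co-occurrence
   matrices in 3x3 sliding windows; nine metrics per window; five
   per-plot statistics (mean, min, max, SD, CV); 45 features per band,
   135 for all three.
6. **Screening** (`borutaRankRuns`, `ocsvmFilter`) — a shadow-feature
   procedure with an 80-of-100 removal rule, then a one-class SVM
   outlier filter.
7. **Modeling** (`fitPredict`, `runAblation`, `runDateSweep`) — five
   regression families over nested feature sets and a per-date sweep;
   accuracy as R^2, RMSE and rRMSE (= 100 RMSE / mean observed).

# Feature definitions and conventions

**Band symbols.** Raw digital numbers are written R, G, B; normalized
bands divide by the *scene-wide* observed maxima (`Rn = R / max(R)`),
and chromatic coordinates renormalize per pixel
(`r = Rn / (Rn + Gn + Bn)`, so `r + g + b = 1`). Indices written with
capital symbols (GRI, GRVI, MGRVI, PPRb, RGBVI, SAVI, VARI, VDVI) are
evaluated on raw DN; the rest (CIVE, COMB1/2, ExG, EXGR, VEG, WI) on
chromatic coordinates. Per-scene rather than per-plot maxima matter:
normalizing within the plot would cancel the very brightness differences
between plots that carry information.

**Undefined pixels.** All-zero (black) pixels are excluded from plot
means. WI is undefined where `|r - g| = 0` and such pixels are dropped
from its mean; ratio indices with zero denominators behave the same
way. Plot means run over *all* valid plot pixels — soil included — so
that canopy cover expresses itself through the means; a canopy-masked
variant is available (`canopyMaskOnly = TRUE`).

**Canopy cover** uses EGI with `G = 0` pixels classed as soil. Raising
the threshold can only shrink the mask (coverage is monotone in the
threshold).

**Crop height.** The bare-ground DEM is one constant per plot: heights
within the plot on the pre-emergence date are split by Otsu's threshold
(computed on a 256-bin histogram of the plot's height range) and the
lower-class mean is the ground elevation; a near-constant sample (range
below tolerance) is degenerate and falls back to the plot mean. The
"normalization" of the height model is clipping negative `DSM - DEM`
values to zero — heights below bare ground are physically impossible.
Plot height is the mean CHM over the canopy mask, with a flagged
whole-plot fallback at zero coverage (a 90th-percentile statistic is
available via `statistic = "p90"`).

**Texture.** Each band is quantized to 32 equal-width levels over the
plot's DN range (constant plots map to level 0); co-occurrences are
counted at distance 1 in the four directions (0, 45, 90, 135 degrees),
symmetrically, and merged — the standard rotation-averaged convention.
Windows are 3x3 and lie fully inside the plot (padding would fabricate
co-occurrences). The nine metrics use the standard definitions (the
matrix "mean" and "variance" are row-marginal moments; energy is the
angular second moment; correlation is defined as 1 for a constant
window, where the marginal variance vanishes). The per-plot CV
statistic (SD/mean over windows) is undefined when a metric's mean is
zero; such values are recorded missing and set to zero when assembling
model matrices.

# Screening

The candidate matrix at the modeling date holds 72 features: the 24
vegetation features, the 45 red-band texture statistics, canopy cover,
crop height and the manually scored lodging level. Lodging and canopy
cover do not take part in the screening and are always kept.

Each of 100 rounds appends one shuffled "shadow" copy of every real
column (shadows keep the marginal distribution exactly, and destroy any
association with the response), fits a random forest, and records each
real feature's out-of-bag permutation importance against the *maximum*
shadow importance of that round. A feature falling below the best
shadow in at least 80 of the 100 rounds is removed. The screening
forests use 500 trees with `mtry = floor(sqrt(p))`: permutation
importances from smaller forests are too noisy against a
maximum-of-70-shadows reference, and large `mtry` makes a correlated
feature family's importance collapse onto its single strongest member —
both would remove many genuinely informative features at the field
sizes used here. (The regression forests used for yield estimation keep
their own convention, 500 trees with `mtry = p/3`.)

The one-class SVM (radial basis, `gamma = 0.001`, support-vector
fraction bound `nu = 0.03`, tolerance `1e-3`) is fitted on the
standardized fused feature matrix *before* the train/validation split —
it is a data-cleaning step, not a modeling step — and rows with negative
decision values are dropped. Standardization is essential: a fixed
radial `gamma` is meaningless across features of wildly different
scales.

# Regression families

All methods see features standardized by training-set statistics (no
leakage) and clamped to eight standard deviations — texture CV
statistics are heavy-tailed and a single plot hundreds of SDs out would
otherwise dominate the linear fits; targets stay in their original
units.

* **PLSR** — SIMPLS with at most five components; the count is chosen by
  leave-one-out cross-validated PRESS.
* **Penalized linear ("Logistic")** — a 10-fold cross-validated lasso
  path (`glmnet`), predicting at the error-minimizing lambda. The
  targets are continuous, so the lambda-path procedure runs under a
  Gaussian likelihood.
* **Random forest** — 500 trees, `mtry = floor(p/3)`.
* **Support-vector regression** — radial kernel, `gamma = 1/p`,
  `epsilon = 0.01`, tolerance 0.001. The response is standardized
  internally (and predictions back-transformed) so that the unit cost
  budget and epsilon tube are meaningful on any target scale.
* **Feed-forward network** — two hidden layers of 200 rectified units,
  per-sample stochastic gradient descent, 10 epochs, learning rate
  0.005, He initialization, response standardized internally, global
  gradient-norm clipping (threshold 50) for stability on wide feature
  sets. Ten epochs is a deliberately shallow training budget; the
  network is not trained to convergence.

The 70/30 split is by plot, with `floor(0.7 n)` training plots. The
date sweep fits every method on every date's full feature inventory
(162 features when all three texture bands are used) and reports the
best date as the highest validation R^2 averaged over methods. The
ablation ladder fits the five nested sets — vegetation indices alone,
then adding texture, canopy cover, crop height, lodging — after
screening, so the fused set has 63 columns when the screening rejects
exactly the nine degenerate texture statistics (24/60/61/62/63 along
the ladder).

# The synthetic trial

No public imagery accompanies the field trial this pipeline targets, so
the package generates one. The generator is first-class, tested code;
its defaults *are* the study conditions for every property test.

**Layout.** 1,805 plots (1,615 cultivar + 190 control) of 1.8 m x
0.8 m on a near-square grid with 0.4 m furrows, 0.05 m ground sampling
distance. The 190 control plots double as the crop-height validation
set. 17 acquisition dates run on a 3-day cadence from day 6 to day 54
after sowing: the first date is pre-emergence (the bare-ground
reference) and the schedule contains day 48, the flowering peak.

**Latent structure.** Every plot draws five independent standard-normal
axes: growth vigor (canopy cover asymptote, logistic timing, final
height), green chroma (canopy G up / R down), blue chroma (canopy B),
texture amplitude and texture granularity (the amplitude and
smooth-versus-speckle mix of the canopy's internal brightness field).
Yield follows
`y = a0 + a1 * vigorComposite + a2 * heightFinal + a3 * (lodging - 1) + noise`,
truncated at zero, where the vigor composite weighs all five axes
equally (0.4 each). This choice is deliberate: in real canopies,
colour, cover, stature *and* texture all carry partially independent
physiological information, and the published importance rankings show
exactly that (texture statistics leading for grain weight, lodging and
greenness indices for grain number). A generator with a single latent
axis would make every feature a proxy of every other and the screening
would collapse onto a handful of winners.

**Calibration.** The only printed population moments of the real trial
are recoverable from its accuracy tables as RMSE / rRMSE ratios: about
59.3 seeds/plant and 9.26 g/plant. The yield intercepts are set so the
simulated means land there, and the dispersion gives coefficients of
variation near 40%. Lodging is skewed toward level 1
(50/20/12/10/8%), is only weakly coupled to height (stem strength, not
stature, drives most lodging), and carries a strong direct yield
penalty — so it holds unique predictive information, as in the real
ranking. Final heights average ~0.8 m with an SD near 0.2 m.

**Rendering.** Soil is darker than canopy in all three bands; within a
plot the tilled soil is uniform (one integer DN per band, with a
per-plot moisture tint), while the background keeps a small jitter.
Canopy palettes are chosen so the excess green index separates the two
classes at the 0.05 threshold *by construction* (pixels are adjusted
after rounding so canopy EGI > 0.05 and soil EGI <= 0.05 always hold).
The canopy mask is a coherent blob covering exactly the plot's canopy
fraction (to rounding), with the four 3x3 plot corners always bare —
row ends abut the furrow — which caps cover slightly below 1. The DSM
adds the plot's current plant height over canopy pixels plus small
measurement noise (2 cm) on a flat 22 m terrain with 1 cm micro-relief.

**What passing tests do and do not show.** The generator emulates the
statistical structure the analysis assumes — class-separable palettes,
logistic growth, registration-true geometry, noise-free plot borders.
It does not emulate registration error, illumination drift between
dates, weeds, mixed boundary pixels, shadowing between plots, or real
photogrammetric artefacts. Green tests therefore validate the
*implementation* of the pipeline and its statistical behaviour under
known truth; they say nothing about accuracy on real imagery.

# A structural consequence: the nine degenerate texture statistics

Because every plot contains at least one constant all-soil 3x3 window
at quantization level 0, nine of the 45 per-plot texture statistics are
pinned at their bounds for *every* plot: `mean_min`, `variance_min`,
`contrast_min`, `dissimilarity_min`, `entropy_min`,
`autocorrelation_min` (all exactly 0), and `energy_max`,
`homogeneity_max`, `correlation_max` (all exactly 1). They are
constants, carry no information, and the shadow-feature screening
removes all nine in every configuration tested — the minimum/maximum
statistics of near-constant metrics, the documented removal pattern.

Three further extreme statistics share their fate, identically for
both yield targets: the minimum window correlation, the minimum energy
and the maximum entropy — the "most disordered window" extremes. These
are extremes of bounded window metrics taken over hundreds of windows
per plot; such extremes concentrate near the edge of their sampling
distribution, so their plot-to-plot variation is mostly extreme-value
noise, and the screening treats them like the pinned nine. The fused
modeling set on the synthetic trial therefore carries 60 features
rather than the nominal 63 of the 72 - 9 bookkeeping; the
nested-ladder counts scale accordingly. This is a property of extreme
statistics under this renderer, not of the screening implementation:
the nine pinned statistics are always among the rejections, and every
non-extreme feature family survives.

# Problem sizes

The test-suite and the acceptance script exercise the pipeline at
reduced field sizes chosen to keep the statistical properties stable:
ground-truth calibration at the full 1,805 plots (no rasters needed);
feature extraction, screening, height validation and the ablation
ladder on reduced fields of 600-750 plots that retain the full
190-plot control set; the 17-date sweep on a 150-plot field. Screening power grows
with field size — at a few hundred plots the max-shadow reference is
high relative to what 70 correlated features can each earn, and
borderline features drift — so the screening checks use the 750-plot
field.

# Known limitations

* The per-scene band maxima make normalized-band features depend on the
  single brightest pixel of a scene; a robust quantile maximum would be
  less fragile on real imagery.
* Minimum/maximum statistics over hundreds of windows concentrate near
  the extreme of their sampling distribution; several are informative
  here only because the generator expresses the texture axes strongly.
  On other data they may behave as near-constants and be screened out.
* The network's 10-epoch budget makes its accuracy sensitive to the
  seed and to feature count; that mirrors its published configuration
  rather than best practice.
* The date sweep refits the same split at every date; temporal
  correlation between dates is ignored by design (single-date models).
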