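# uavyield

Plot-level estimation of soybean **yield parameters** — grain number of
seeds per plant and grain weight per plant — from multi-date UAV RGB
orthomosaics and photogrammetric surface models, under **lodging**
(ordinal severity 1–5, which depresses yield).

Large germplasm trials (here: 1,805 two-row plots of 1.8 m × 0.8 m,
imaged at 17 dates through the season) cannot rely on plot yield, which
is dominated by chance factors at that plot size. This package
implements the full analysis chain from registered rasters to per-plot
yield-parameter estimates:

* **Per-plot feature extraction** — 24 RGB vegetation features
  (15 named indices such as ExG = 2g − r − b, CIVE, GRVI, VARI, plus
  normalized bands and raw band means), excess-green canopy cover
  (EGI = (2G − R − B)/G > 0.05), crop height from a crop height model
  (CHM = DSM − DEM, bare ground per plot from an Otsu split of the
  pre-emergence surface model), and 135 gray-level co-occurrence matrix
  (GLCM) texture statistics (9 metrics × 3 bands × 5 plot statistics;
  45 on the red band alone).
* **Feature screening** — a shadow-feature (Boruta-style) procedure:
  100 rounds of random-forest permutation importance against shuffled
  shadow copies, removing features that rank below the best shadow in
  ≥ 80 of 100 rounds; then a one-class SVM (RBF, γ = 0.001, ν = 0.03)
  that drops outlier plots.
* **Modeling** — five regression families with fixed hyperparameters
  (PLSR with ≤ 5 components by leave-one-out PRESS; a 10-fold
  cross-validated penalized linear model; a 500-tree random forest;
  RBF support-vector regression; a 2 × 200 feed-forward network), a
  70/30 plot split, and accuracy as R², RMSE and rRMSE
  (= 100 · RMSE / mean observed).
* **Experiments** — the 17-date sweep (which acquisition date predicts
  best; flowering, day 48, under the default conditions) and the
  nested feature-set ablation VIs → +texture → +canopy cover → +height
  → +lodging (24/60/61/62/63 features after screening).
* **A synthetic trial generator** — no public imagery accompanies the
  real trial, so `simulateSeason()` renders registered RGB + DSM scene
  stacks with known ground truth (logistic canopy growth, five latent
  plot axes, calibrated yield populations: ≈ 59.3 seeds/plant,
  ≈ 9.26 g/plant, CV ≈ 40 %). Every stage of the pipeline is tested
  against this generator's truth.

See the methods vignette (`vignettes/uavyield-methods.Rmd`) for the
model details, conventions and design decisions.

## Worked example

Simulate a small trial, extract the day-48 features, and fit the five
models on the fused feature set:

```r
library(uavyield)

design <- fieldDesign(nCultivarPlots = 270, nControlPlots = 30,
                      dates = c(6L, 48L))
sim <- simulateSeason(design, seed = 1)

dem <- bareDEM(sim$scenes[["6"]], sim$layout)   # bare ground, day 6
ft  <- extractPlotFeatures(sim$scenes[["48"]], sim$layout, dem,
                           textureBands = "R")
ft
#> FeatureTable: 72 features x 300 plots (day 48)
#>   CC:1  CHM:1  LODGING:1  TI:45  VI:24

rep <- screenFeatures(ft, "grain_number", seed = 1)
rep
#> ScreeningReport: 70 features screened over 100 runs (cutoff 80 )
#>   removed: 21 | kept: 49 | excluded from screening: 2

ab <- runAblation(ft, reports = list(grain_number = rep),
                  targets = "grain_number", seed = 1)
subset(ab$table, featureSet == "VIs+TI+CC+CHM+Lodging" &
                 split == "validation")
#>               featureSet   method       target      split    r2 rmse rrmse
#> 42 VIs+TI+CC+CHM+Lodging     PLSR grain_number validation 0.579 16.1  26.6
#> 44 VIs+TI+CC+CHM+Lodging Logistic grain_number validation 0.600 15.7  25.9
#> 46 VIs+TI+CC+CHM+Lodging      RFR grain_number validation 0.380 19.5  32.2
#> 48 VIs+TI+CC+CHM+Lodging      SVM grain_number validation 0.388 19.4  32.0
#> 50 VIs+TI+CC+CHM+Lodging      DNN grain_number validation 0.372 19.7  32.5
```

The printed `r2`/`rmse`/`rrmse` are validation-set accuracy of each
method on the fused post-screening feature set: `rmse` in seeds/plant,
`rrmse` as a percentage of the mean observed grain number. At this
deliberately small 300-plot field the screening is conservative (it
keeps 49 of 70 candidates); on the larger fields the package uses for
its own checks it keeps about 60 — see the methods vignette on how
screening power scales with field size.

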