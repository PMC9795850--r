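#' @import methods
#' @importFrom stats plogis qnorm rnorm runif sd quantile var predict
#'   coef lm complete.cases
#' @importFrom utils read.csv write.csv head
NULL

## ---------------------------------------------------------------------------
## FieldDesign
## ---------------------------------------------------------------------------

#' Field trial design
#'
#' Describes the geometry and acquisition schedule of a (synthetic) field
#' trial: number of cultivar and control plots, plot rectangle size, furrow
#' gaps, ground sampling distance and the days-after-sowing flight schedule.
#' The defaults mirror a 1,805-plot soybean trial (1,615 cultivar + 190
#' control plots of 1.8 m x 0.8 m) imaged at 17 time points on a 3-day
#' cadence spanning pre-emergence through late flowering.
#'
#' @slot nCultivarPlots integer, number of cultivar plots.
#' @slot nControlPlots integer, number of control plots (also used as the
#'   crop-height validation set).
#' @slot plotLength numeric, plot length in metres (along-row, y axis).
#' @slot plotWidth numeric, plot width in metres (x axis).
#' @slot furrowGap numeric, gap between neighbouring plot rectangles (m).
#' @slot margin numeric, bare margin around the field (m).
#' @slot gsd numeric, ground sampling distance (m/pixel).
#' @slot dates integer vector, days after sowing of each acquisition,
#'   strictly increasing; the first date must be pre-emergence.
#' @slot baseElevation numeric, terrain elevation above datum (m).
#' @exportClass FieldDesign
setClass("FieldDesign",
  representation(
    nCultivarPlots = "integer",
    nControlPlots  = "integer",
    plotLength     = "numeric",
    plotWidth      = "numeric",
    furrowGap      = "numeric",
    margin         = "numeric",
    gsd            = "numeric",
    dates          = "integer",
    baseElevation  = "numeric"
  )
)

setValidity("FieldDesign", function(object) {
  msg <- character()
  if (object@nCultivarPlots < 1L)
    msg <- c(msg, "nCultivarPlots must be >= 1")
  if (object@nControlPlots < 0L)
    msg <- c(msg, "nControlPlots must be >= 0")
  if (object@plotLength <= 0 || object@plotWidth <= 0)
    msg <- c(msg, "plot dimensions must be positive")
  if (object@gsd <= 0)
    msg <- c(msg, "gsd must be positive")
  if (object@furrowGap < 0)
    msg <- c(msg, "furrowGap must be non-negative")
  if (length(object@dates) < 1L || any(diff(object@dates) <= 0L))
    msg <- c(msg, "dates must be non-empty and strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a field trial design
#'
#' @param nCultivarPlots number of cultivar plots (default 1615).
#' @param nControlPlots number of control plots (default 190).
#' @param plotLength plot length in metres (default 1.8).
#' @param plotWidth plot width in metres (default 0.8).
#' @param furrowGap furrow gap between plots in metres (default 0.4).
#' @param margin bare soil margin around the field in metres (default 1).
#' @param gsd ground sampling distance in metres per pixel (default 0.05).
#' @param dates integer days after sowing; default 17 dates on a 3-day
#'   cadence from day 6 to day 54 (includes the day-48 flowering peak; the
#'   first date is pre-emergence and serves as the bare-ground reference).
#' @param baseElevation terrain elevation in metres (default 22).
#' @return A [FieldDesign-class] object.
#' @examples
#' d <- fieldDesign(nCultivarPlots = 10, nControlPlots = 2)
#' nPlots(d)
#' @export
fieldDesign <- function(nCultivarPlots = 1615L, nControlPlots = 190L,
                        plotLength = 1.8, plotWidth = 0.8,
                        furrowGap = 0.4, margin = 1,
                        gsd = 0.05,
                        dates = seq(6L, 54L, by = 3L),
                        baseElevation = 22) {
  if (!length(nCultivarPlots) || is.na(nCultivarPlots) || nCultivarPlots < 1)
    stop("nCultivarPlots must be a positive count")
  if (is.na(nControlPlots) || nControlPlots < 0)
    stop("nControlPlots must be a non-negative count")
  if (gsd <= 0) stop("gsd must be positive")
  new("FieldDesign",
      nCultivarPlots = as.integer(nCultivarPlots),
      nControlPlots = as.integer(nControlPlots),
      plotLength = plotLength, plotWidth = plotWidth,
      furrowGap = furrowGap, margin = margin, gsd = gsd,
      dates = as.integer(dates), baseElevation = baseElevation)
}

#' @describeIn fieldDesign total number of plots in a design.
#' @param design a [FieldDesign-class] object.
#' @export
nPlots <- function(design) design@nCultivarPlots + design@nControlPlots

setMethod("show", "FieldDesign", function(object) {
  cat("FieldDesign:", nPlots(object), "plots (",
      object@nCultivarPlots, "cultivar +", object@nControlPlots,
      "control ),", object@plotLength, "x", object@plotWidth, "m\n")
  cat("  GSD", object@gsd, "m/px;", length(object@dates),
      "dates (days", object@dates[1], "-",
      object@dates[length(object@dates)], "after sowing)\n")
})

## ---------------------------------------------------------------------------
## GrowthParams
## ---------------------------------------------------------------------------

#' Growth and yield model parameters for the synthetic field
#'
#' Parameters of the generative model behind the synthetic trial. Each
#' plot carries five independent latent axes: growth vigor (canopy cover
#' and height), green chroma, blue chroma, and two canopy-structure axes
#' (texture amplitude and texture granularity). Their weighted sum is the
#' plot's physiological vigor composite. Canopy growth and plant height
#' follow logistic curves; lodging is ordinal, drawn from a latent score
#' increasing (weakly) with final height; the yield parameters follow
#'
#' `y = a0 + a1*vigorComposite + a2*heightFinal + a3*(lodging-1) + eps`,
#'
#' truncated at zero, separately for grain number (seeds/plant) and grain
#' weight (g/plant). The lodging slope must be non-positive (lodging
#' depresses yield). Because every latent axis is expressed in a distinct
#' image channel (cover, greenness, blueness, texture amplitude, texture
#' grain) and all contribute to yield, every feature family carries
#' partially independent predictive information — the structure the
#' published importance rankings show.
#'
#' @slot vigorSd numeric, SD of every latent axis (mean 0).
#' @slot canopyAsymBase,canopyAsymSlope numeric, canopy-cover asymptote
#'   `= clamp(base + slope*vigor, 0.05, canopyAsymMax)`.
#' @slot canopyAsymMax numeric, upper bound of the asymptote in (0, 1].
#' @slot canopyMidBase,canopyMidSlope numeric, logistic midpoint day
#'   `= base + slope*vigor`.
#' @slot canopyRate numeric, logistic growth rate (1/day).
#' @slot heightMaxBase,heightMaxSlope,heightMaxSd numeric, final plant
#'   height `= max(0.2, base + slope*vigor + N(0, sd))` in metres.
#' @slot heightMid,heightRate numeric, height logistic midpoint (day) and
#'   rate (1/day).
#' @slot lodgingProbs numeric length-5, target marginal distribution of
#'   lodging levels 1..5.
#' @slot lodgingSlope numeric, weight of standardized final height in the
#'   latent lodging score (higher plants lodge more).
#' @slot grainNumberCoef,grainWeightCoef numeric length-4 `(a0,a1,a2,a3)`
#'   with `a3 <= 0`.
#' @slot grainNumberSd,grainWeightSd numeric, yield noise SDs (> 0).
#' @slot vigorWeights numeric length-5, weights of the latent axes
#'   (vigor, chroma, blueChroma, structAmp, structGran) in the yield
#'   vigor composite.
#' @slot soilRGB,canopyRGB numeric length-3, mean palettes (DN).
#' @slot soilJitterSd numeric, per-pixel soil colour SD (DN); small, so
#'   bare tilled soil is locally uniform.
#' @slot chromaShiftR,chromaShiftG numeric, canopy R/G mean shift per
#'   unit green chroma (DN).
#' @slot blueShiftB numeric, canopy B mean shift per unit blue chroma.
#' @slot canopyShiftG numeric, green-band canopy brightening per unit
#'   growth vigor.
#' @slot structAmpBase,structAmpSlope numeric, canopy texture amplitude
#'   `= clamp(base + slope*structAmp, 1.5, 12)` (DN SD): plots with more
#'   internal leaf/shadow structure show stronger texture.
#' @slot granularitySlope numeric, logistic weight of the granularity
#'   axis in the smooth-versus-speckle mix of the canopy texture field.
#' @slot bandScale numeric length-3, relative texture amplitude per band.
#' @slot plotColorSd numeric, SD of the per-plot canopy colour deviation
#'   (DN, independent per band): cultivar-specific hue differences that do
#'   not average out over pixels.
#' @slot soilTintSd numeric, SD of the per-plot soil tint (DN per band):
#'   moisture/organic-matter background variation, constant within a
#'   plot.
#' @slot stageMid,stageRate numeric, logistic stage window
#'   `plogis(rate * (day - mid))` scaling how strongly the chroma and
#'   texture axes are expressed in the imagery: cultivar colour and
#'   canopy-structure differences develop toward flowering.
#' @slot terrainSd,dsmNoiseSd,canopySurfaceSd numeric, elevation noise
#'   terms (m): static micro-relief, per-date DSM measurement noise, and
#'   within-canopy surface roughness.
#' @exportClass GrowthParams
setClass("GrowthParams",
  representation(
    vigorSd = "numeric",
    canopyAsymBase = "numeric", canopyAsymSlope = "numeric",
    canopyAsymMax = "numeric",
    canopyMidBase = "numeric", canopyMidSlope = "numeric",
    canopyRate = "numeric",
    heightMaxBase = "numeric", heightMaxSlope = "numeric",
    heightMaxSd = "numeric",
    heightMid = "numeric", heightRate = "numeric",
    lodgingProbs = "numeric", lodgingSlope = "numeric",
    grainNumberCoef = "numeric", grainNumberSd = "numeric",
    grainWeightCoef = "numeric", grainWeightSd = "numeric",
    vigorWeights = "numeric",
    soilRGB = "numeric", canopyRGB = "numeric",
    soilJitterSd = "numeric",
    chromaShiftR = "numeric", chromaShiftG = "numeric",
    blueShiftB = "numeric", canopyShiftG = "numeric",
    structAmpBase = "numeric", structAmpSlope = "numeric",
    granularitySlope = "numeric", bandScale = "numeric",
    plotColorSd = "numeric", soilTintSd = "numeric",
    stageMid = "numeric", stageRate = "numeric",
    terrainSd = "numeric", dsmNoiseSd = "numeric",
    canopySurfaceSd = "numeric"
  )
)

setValidity("GrowthParams", function(object) {
  msg <- character()
  if (object@canopyAsymMax <= 0 || object@canopyAsymMax > 1)
    msg <- c(msg, "canopy asymptote bound must be in (0, 1]")
  if (object@heightMaxBase < 0)
    msg <- c(msg, "heights must be >= 0")
  if (length(object@lodgingProbs) != 5L || any(object@lodgingProbs < 0) ||
      abs(sum(object@lodgingProbs) - 1) > 1e-8)
    msg <- c(msg, "lodgingProbs must be 5 non-negative values summing to 1")
  if (object@grainNumberCoef[4] > 0 || object@grainWeightCoef[4] > 0)
    msg <- c(msg, "lodging slope of the yield models must be <= 0")
  if (object@grainNumberSd <= 0 || object@grainWeightSd <= 0)
    msg <- c(msg, "yield noise SDs must be > 0")
  if (length(object@soilRGB) != 3L || length(object@canopyRGB) != 3L)
    msg <- c(msg, "palettes must have 3 channels")
  if (length(object@vigorWeights) != 5L)
    msg <- c(msg, "vigorWeights must have 5 entries")
  if (length(object@bandScale) != 3L)
    msg <- c(msg, "bandScale must have 3 entries")
  if (length(msg)) msg else TRUE
})

#' Construct growth/yield parameters for the synthetic field
#'
#' Defaults are calibrated so that the simulated population reproduces the
#' only printed moments of the real trial: mean grain number ~59.3
#' seeds/plant and mean grain weight ~9.26 g/plant with coefficients of
#' variation in the 40-45% range, and a lodging marginal skewed toward
#' level 1 (50/20/12/10/8%). The canopy palette separates from soil at
#' excess-green index 0.05 by construction, and soil is darker than canopy
#' in all three bands with a small jitter so that bare-soil image patches
#' are locally uniform.
#'
#' @param vigorSd SD of latent vigor.
#' @param canopyAsymBase,canopyAsymSlope,canopyAsymMax canopy asymptote
#'   model (fraction of plot area).
#' @param canopyMidBase,canopyMidSlope,canopyRate canopy logistic timing.
#' @param heightMaxBase,heightMaxSlope,heightMaxSd final height model (m).
#' @param heightMid,heightRate height logistic timing.
#' @param lodgingProbs target lodging marginal (levels 1..5).
#' @param lodgingSlope height weight in the latent lodging score (weak by
#'   default: stem strength, not stature, drives most lodging).
#' @param grainNumberCoef,grainNumberSd grain-number model
#'   `(a0, a1, a2, a3)` and noise SD.
#' @param grainWeightCoef,grainWeightSd grain-weight model and noise SD.
#' @param vigorWeights weights of the five latent axes in the yield
#'   vigor composite.
#' @param soilRGB,canopyRGB mean palettes (DN, 0-255).
#' @param soilJitterSd,chromaShiftR,chromaShiftG,blueShiftB,canopyShiftG
#'   pixel/plot-level palette variation (DN).
#' @param structAmpBase,structAmpSlope,granularitySlope,bandScale canopy
#'   texture model.
#' @param terrainSd,dsmNoiseSd,canopySurfaceSd elevation noise terms (m).
#' @return A [GrowthParams-class] object.
#' @examples
#' p <- growthParams()
#' p@grainNumberCoef
#' @export
growthParams <- function(vigorSd = 1,
                         canopyAsymBase = 0.78, canopyAsymSlope = 0.05,
                         canopyAsymMax = 0.92,
                         canopyMidBase = 30, canopyMidSlope = -1,
                         canopyRate = 0.22,
                         heightMaxBase = 0.82, heightMaxSlope = 0.18,
                         heightMaxSd = 0.12,
                         heightMid = 32, heightRate = 0.25,
                         lodgingProbs = c(0.50, 0.20, 0.12, 0.10, 0.08),
                         lodgingSlope = 0.8,
                         grainNumberCoef = c(38.5, 18, 40, -10),
                         grainNumberSd = 14,
                         grainWeightCoef = c(5.95, 2.8, 6.2, -1.5),
                         grainWeightSd = 2.2,
                         vigorWeights = c(vigor = 0.4, chroma = 0.4,
                                          blueChroma = 0.4,
                                          structAmp = 0.4,
                                          structGran = 0.4),
                         soilRGB = c(62, 46, 38),
                         canopyRGB = c(100, 150, 72),
                         soilJitterSd = 0.1,
                         chromaShiftR = -6, chromaShiftG = 10,
                         blueShiftB = 10, canopyShiftG = 6,
                         structAmpBase = 5, structAmpSlope = 2,
                         granularitySlope = 1.5,
                         bandScale = c(1, 1, 0.85),
                         plotColorSd = 2.5, soilTintSd = 5,
                         stageMid = 40, stageRate = 0.5,
                         terrainSd = 0.01, dsmNoiseSd = 0.02,
                         canopySurfaceSd = 0.03) {
  new("GrowthParams",
      vigorSd = vigorSd,
      canopyAsymBase = canopyAsymBase, canopyAsymSlope = canopyAsymSlope,
      canopyAsymMax = canopyAsymMax,
      canopyMidBase = canopyMidBase, canopyMidSlope = canopyMidSlope,
      canopyRate = canopyRate,
      heightMaxBase = heightMaxBase, heightMaxSlope = heightMaxSlope,
      heightMaxSd = heightMaxSd,
      heightMid = heightMid, heightRate = heightRate,
      lodgingProbs = lodgingProbs, lodgingSlope = lodgingSlope,
      grainNumberCoef = grainNumberCoef, grainNumberSd = grainNumberSd,
      grainWeightCoef = grainWeightCoef, grainWeightSd = grainWeightSd,
      vigorWeights = unname(vigorWeights),
      soilRGB = soilRGB, canopyRGB = canopyRGB,
      soilJitterSd = soilJitterSd,
      chromaShiftR = chromaShiftR, chromaShiftG = chromaShiftG,
      blueShiftB = blueShiftB, canopyShiftG = canopyShiftG,
      structAmpBase = structAmpBase, structAmpSlope = structAmpSlope,
      granularitySlope = granularitySlope, bandScale = bandScale,
      plotColorSd = plotColorSd, soilTintSd = soilTintSd,
      stageMid = stageMid, stageRate = stageRate,
      terrainSd = terrainSd, dsmNoiseSd = dsmNoiseSd,
      canopySurfaceSd = canopySurfaceSd)
}

## ---------------------------------------------------------------------------
## SceneStack
## ---------------------------------------------------------------------------

#' A registered RGB + DSM raster pair for one acquisition date
#'
#' Holds the 3-band RGB digital-number grid, the single-band digital
#' surface model (metres), and the affine map transform for one flight
#' date. Pixel coordinates are 0-based, row-major, origin at the top-left
#' corner; the transform is axis-aligned (no rotation).
#'
#' @slot date integer, days after sowing.
#' @slot rgb numeric array `rows x cols x 3` of DN in `[0, 255]`.
#' @slot dsm numeric matrix `rows x cols` of elevations (m).
#' @slot transform named numeric: `xres` (m/px, > 0), `yres` (m/px, < 0),
#'   `xmin`, `ymax` — map coordinates of the top-left raster corner (edge,
#'   not pixel centre).
#' @slot nodata numeric, sentinel for missing DSM values.
#' @exportClass SceneStack
setClass("SceneStack",
  representation(
    date = "integer",
    rgb = "array",
    dsm = "matrix",
    transform = "numeric",
    nodata = "numeric"
  )
)

setValidity("SceneStack", function(object) {
  msg <- character()
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "rgb must be a rows x cols x 3 array")
  else if (!identical(d[1:2], dim(object@dsm)))
    msg <- c(msg, "rgb and dsm must share the same grid")
  rng <- range(object@rgb)
  if (rng[1] < 0 || rng[2] > 255)
    msg <- c(msg, "rgb DN must lie in [0, 255]")
  tr <- object@transform
  need <- c("xres", "yres", "xmin", "ymax")
  if (!all(need %in% names(tr)))
    msg <- c(msg, "transform must name xres, yres, xmin, ymax")
  else if (tr["xres"] <= 0 || tr["yres"] >= 0)
    msg <- c(msg, "transform must be invertible (xres > 0, yres < 0)")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneStack
#'
#' @param date integer days after sowing.
#' @param rgb rows x cols x 3 DN array.
#' @param dsm rows x cols elevation matrix (m).
#' @param transform named numeric (`xres`, `yres`, `xmin`, `ymax`).
#' @param nodata missing-value sentinel (default -9999).
#' @return A [SceneStack-class].
#' @export
SceneStack <- function(date, rgb, dsm, transform, nodata = -9999) {
  new("SceneStack", date = as.integer(date), rgb = rgb, dsm = dsm,
      transform = transform[c("xres", "yres", "xmin", "ymax")],
      nodata = nodata)
}

#' @describeIn SceneStack acquisition date (days after sowing).
#' @param scene a [SceneStack-class].
#' @export
sceneDate <- function(scene) scene@date

#' @describeIn SceneStack the RGB DN array.
#' @export
sceneRGB <- function(scene) scene@rgb

#' @describeIn SceneStack the DSM matrix (m).
#' @export
sceneDSM <- function(scene) scene@dsm

#' @describeIn SceneStack the affine transform.
#' @export
sceneTransform <- function(scene) scene@transform

setMethod("show", "SceneStack", function(object) {
  d <- dim(object@dsm)
  cat("SceneStack: day", object@date, "-", d[1], "x", d[2],
      "px @", object@transform[["xres"]], "m/px\n")
  cat("  DSM range:", paste(signif(range(object@dsm), 6), collapse = " - "),
      "m\n")
})

## ---------------------------------------------------------------------------
## FeatureTable (SummarizedExperiment subclass)
## ---------------------------------------------------------------------------

#' Plot-by-feature table
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass
#' storing the plot-level feature matrix for one acquisition date:
#' features are rows (with a `group` label in `rowData`, one of
#' `"VI"`, `"TI"`, `"CC"`, `"CHM"`, `"LODGING"`), plots are columns (with
#' ground truth and identifiers in `colData`).
#'
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "must contain a 'features' assay")
  rd <- SummarizedExperiment::rowData(object)
  if (!"group" %in% colnames(rd))
    msg <- c(msg, "rowData must contain a 'group' column")
  else if (!all(rd$group %in% c("VI", "TI", "CC", "CHM", "LODGING")))
    msg <- c(msg, "feature groups must be VI, TI, CC, CHM or LODGING")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param features numeric matrix, features x plots.
#' @param groups character vector of feature-group labels, one per row
#'   (`VI`, `TI`, `CC`, `CHM`, `LODGING`).
#' @param plotData data.frame of per-plot metadata (one row per column of
#'   `features`), typically the plot table with ground truth.
#' @param date integer, acquisition date (days after sowing).
#' @return A [FeatureTable-class].
#' @export
FeatureTable <- function(features, groups, plotData, date = NA_integer_) {
  stopifnot(nrow(features) == length(groups),
            ncol(features) == nrow(plotData))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = features),
    rowData = S4Vectors::DataFrame(group = groups),
    colData = S4Vectors::DataFrame(plotData),
    metadata = list(date = as.integer(date)))
  new("FeatureTable", se)
}

#' @describeIn FeatureTable feature-group label per feature row.
#' @param x a [FeatureTable-class].
#' @export
featureGroups <- function(x) SummarizedExperiment::rowData(x)$group

#' @describeIn FeatureTable the features x plots matrix.
#' @export
featureMatrix <- function(x) SummarizedExperiment::assay(x, "features")

setMethod("show", "FeatureTable", function(object) {
  grp <- table(featureGroups(object))
  cat("FeatureTable: ", nrow(object), " features x ", ncol(object),
      " plots (day ", S4Vectors::metadata(object)$date, ")\n", sep = "")
  cat(" ", paste(names(grp), grp, sep = ":", collapse = "  "), "\n")
})

## ---------------------------------------------------------------------------
## ScreeningReport
## ---------------------------------------------------------------------------

#' Shadow-feature screening report
#'
#' Records, for every screened feature, its permutation-importance history
#' over the repeated shadow runs, the number of runs in which it ranked
#' below the best shadow feature, its average importance rank, and the
#' keep/remove decision under the cutoff rule (remove iff the feature fell
#' below the best shadow in at least `cutoff` of `nRuns` runs). Features
#' excluded from screening (lodging, canopy cover) are always kept.
#'
#' @slot importanceHistory numeric matrix, features x runs.
#' @slot timesBelowBestShadow integer vector per feature.
#' @slot decision character vector, `"keep"` or `"remove"`.
#' @slot avgRank numeric average rank of each feature (1 = most important).
#' @slot excluded character, feature names excluded from screening.
#' @slot nRuns,cutoff integer, number of runs and removal cutoff.
#' @exportClass ScreeningReport
setClass("ScreeningReport",
  representation(
    importanceHistory = "matrix",
    timesBelowBestShadow = "integer",
    decision = "character",
    avgRank = "numeric",
    excluded = "character",
    nRuns = "integer",
    cutoff = "integer"
  )
)

setValidity("ScreeningReport", function(object) {
  msg <- character()
  if (any(object@timesBelowBestShadow > object@nRuns))
    msg <- c(msg, "timesBelowBestShadow cannot exceed nRuns")
  rem <- object@decision == "remove"
  if (any(rem & object@timesBelowBestShadow < object@cutoff))
    msg <- c(msg, "removed features must be below the best shadow >= cutoff times")
  if (!all(object@decision %in% c("keep", "remove")))
    msg <- c(msg, "decision must be keep or remove")
  if (length(msg)) msg else TRUE
})

#' @describeIn borutaRankRuns keep/remove decision per screened feature.
#' @param report a [ScreeningReport-class].
#' @export
screeningDecisions <- function(report) {
  stats::setNames(report@decision, rownames(report@importanceHistory))
}

#' @describeIn borutaRankRuns names of features kept (screened features
#'   decided "keep" plus the screening-excluded features).
#' @export
keptFeatures <- function(report) {
  c(names(screeningDecisions(report))[report@decision == "keep"],
    report@excluded)
}

#' @describeIn borutaRankRuns names of rejected features.
#' @export
rejectedFeatures <- function(report) {
  names(screeningDecisions(report))[report@decision == "remove"]
}

setMethod("show", "ScreeningReport", function(object) {
  cat("ScreeningReport:", nrow(object@importanceHistory),
      "features screened over", object@nRuns, "runs (cutoff",
      object@cutoff, ")\n")
  cat("  removed:", sum(object@decision == "remove"),
      "| kept:", sum(object@decision == "keep"),
      "| excluded from screening:", length(object@excluded), "\n")
})

## ---------------------------------------------------------------------------
## ModelResult
## ---------------------------------------------------------------------------

#' Result of one model fit
#'
#' Holds train and validation metrics (R2, RMSE, rRMSE in %) and the
#' per-plot predictions for one regression method, feature set and target.
#'
#' @slot method character, one of `PLSR`, `Logistic`, `RFR`, `SVM`, `DNN`.
#' @slot featureSet character label (e.g. `"VIs+TI+CC"`).
#' @slot target character, `grainNumber` or `grainWeight`.
#' @slot train,validation named numeric `(r2, rmse, rrmse)`.
#' @slot predictions data.frame with `plotId`, `split`, `observed`,
#'   `predicted`.
#' @exportClass ModelResult
setClass("ModelResult",
  representation(
    method = "character",
    featureSet = "character",
    target = "character",
    train = "numeric",
    validation = "numeric",
    predictions = "data.frame"
  )
)

setValidity("ModelResult", function(object) {
  msg <- character()
  for (s in list(object@train, object@validation)) {
    if (!all(c("r2", "rmse", "rrmse") %in% names(s)))
      msg <- c(msg, "metrics must name r2, rmse, rrmse")
    else {
      if (s[["rmse"]] < 0 || s[["rrmse"]] < 0)
        msg <- c(msg, "RMSE and rRMSE must be >= 0")
      if (s[["r2"]] > 1 + 1e-12)
        msg <- c(msg, "R2 cannot exceed 1")
    }
  }
  sp <- split(object@predictions$plotId, object@predictions$split)
  if (length(sp) == 2L && length(intersect(sp[[1]], sp[[2]])))
    msg <- c(msg, "train and validation plots must be disjoint")
  if (length(msg)) msg else TRUE
})

#' @describeIn fitPredict named metric vector for one split
#'   (`"train"` or `"validation"`).
#' @param result a [ModelResult-class].
#' @param split `"train"` or `"validation"`.
#' @export
modelMetrics <- function(result, split = c("validation", "train")) {
  split <- match.arg(split)
  slot(result, split)
}

#' @describeIn fitPredict predictions data.frame of a fit.
#' @export
modelPredictions <- function(result) result@predictions

setMethod("show", "ModelResult", function(object) {
  cat("ModelResult:", object@method, "|", object@featureSet, "|",
      object@target, "\n")
  cat(sprintf("  train      R2=%.3f RMSE=%.3f rRMSE=%.2f%%\n",
              object@train[["r2"]], object@train[["rmse"]],
              object@train[["rrmse"]]))
  cat(sprintf("  validation R2=%.3f RMSE=%.3f rRMSE=%.2f%%\n",
              object@validation[["r2"]], object@validation[["rmse"]],
              object@validation[["rrmse"]]))
})
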