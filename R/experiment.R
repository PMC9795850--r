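## Orchestration: per-date feature extraction, screening at the modeling
## date, the nested feature-set ablation ladder, the acquisition-date
## sweep, and report writing.

#' Bare-ground DEM for every plot
#'
#' Applies [estimateBareDEM()] to each plot on the pre-emergence scene.
#'
#' @param earlyScene first-date [SceneStack-class].
#' @param plots plot table.
#' @return named numeric vector of bare-ground elevations (m).
#' @export
bareDEM <- function(earlyScene, plots) {
  out <- vapply(seq_len(nrow(plots)), function(i)
    estimateBareDEM(earlyScene, plots[i, ]), numeric(1))
  names(out) <- plots$plot_id
  out
}

#' Extract the plot-level feature table for one scene
#'
#' Clips every plot from the scene and assembles the vegetation block
#' (24 features), the GLCM texture block (45 per requested band), canopy
#' cover, crop height (CHM aggregated over the canopy mask against the
#' supplied bare-ground DEM), and the manually scored lodging level into
#' a [FeatureTable-class]. Undefined texture CV statistics (zero-mean
#' metrics) are set to zero so the matrix stays numeric.
#'
#' @param scene a [SceneStack-class].
#' @param plots plot table (with `lodging` and yield columns filled for
#'   modeling use).
#' @param dem named per-plot bare-ground elevations from [bareDEM()].
#' @param textureBands bands for the texture block (default `"R"`,
#'   matching the 72-feature modeling inventory; use
#'   `c("R", "G", "B")` for the full 135-variable block).
#' @param config a [glcmConfig()].
#' @return a [FeatureTable-class] with feature groups VI, TI, CC, CHM,
#'   LODGING.
#' @export
extractPlotFeatures <- function(scene, plots, dem,
                                textureBands = "R",
                                config = glcmConfig()) {
  stopifnot(is(scene, "SceneStack"))
  if (!all(plots$plot_id %in% names(dem)))
    stop("dem must cover every plot")
  sceneMax <- c(max(scene@rgb[, , 1]), max(scene@rgb[, , 2]),
                max(scene@rgb[, , 3]))
  featList <- lapply(seq_len(nrow(plots)), function(i) {
    blk <- clipPlot(scene, plots[i, ])
    vi <- plotVIFeatures(blk, maxima = sceneMax)
    ti <- plotTextureFeatures(blk, bands = textureBands, config = config)
    cc <- canopyCover(blk)
    chm <- computeCHM(blk$dsm, dem[[plots$plot_id[i]]])
    ph <- plotHeight(chm, cc$mask)
    c(vi, ti, CC = cc$fraction, CHM = ph$height,
      Lodging = as.numeric(plots$lodging[i]))
  })
  m <- do.call(cbind, featList)
  colnames(m) <- plots$plot_id
  m[!is.finite(m)] <- 0
  nTI <- 45L * length(textureBands)
  groups <- c(rep("VI", 24L), rep("TI", nTI), "CC", "CHM", "LODGING")
  FeatureTable(m, groups, plots, date = sceneDate(scene))
}

#' Screen the candidate features of a feature table
#'
#' Runs the shadow-feature procedure ([borutaRankRuns()]) on the
#' candidate matrix of `ft` against one yield target. Lodging and canopy
#' cover do not participate in the screening (they are always kept).
#'
#' @param ft a [FeatureTable-class].
#' @param target `"grain_number"` or `"grain_weight"` (a `colData`
#'   column).
#' @param nRuns,cutoff,numTrees,seed passed to [borutaRankRuns()].
#' @return a [ScreeningReport-class].
#' @export
screenFeatures <- function(ft, target = "grain_number", nRuns = 100L,
                           cutoff = 80L, numTrees = 500L, seed = 1L) {
  X <- t(featureMatrix(ft))
  y <- SummarizedExperiment::colData(ft)[[target]]
  if (is.null(y)) stop("unknown target: ", target)
  keep <- stats::complete.cases(X) & !is.na(y)
  borutaRankRuns(X[keep, , drop = FALSE], y[keep],
                 nRuns = nRuns, cutoff = cutoff,
                 exclude = c("Lodging", "CC"),
                 numTrees = numTrees, seed = seed)
}

#' The nested feature-set ladder
#'
#' @return named list of feature-group vectors, from vegetation indices
#'   alone to the full fusion with lodging; each step adds exactly one
#'   group.
#' @export
ablationPlan <- function() {
  list("VIs" = "VI",
       "VIs+TI" = c("VI", "TI"),
       "VIs+TI+CC" = c("VI", "TI", "CC"),
       "VIs+TI+CC+CHM" = c("VI", "TI", "CC", "CHM"),
       "VIs+TI+CC+CHM+Lodging" = c("VI", "TI", "CC", "CHM", "LODGING"))
}

## Kept feature names of `ft` for a target, in table order.
keptForTarget <- function(ft, report) {
  keep <- keptFeatures(report)
  rownames(ft)[rownames(ft) %in% keep]
}

#' Run the feature-set ablation ladder
#'
#' For each yield target: applies the screening decision, optionally
#' removes outlier plots with the one-class SVM (fitted once on the full
#' fused matrix before the split), splits plots 70/30, and fits every
#' method on every nested feature set of [ablationPlan()].
#'
#' @param ft a [FeatureTable-class] for the modeling date.
#' @param reports named list of [ScreeningReport-class], one per target
#'   (names = targets). Computed with [screenFeatures()] when `NULL`.
#' @param targets response columns (default both yield parameters).
#' @param methods subset of [yieldMethods()].
#' @param seed integer seed.
#' @param applyOCSVM logical, apply the one-class SVM filter.
#' @param trainFraction train share (default 0.7).
#' @param nRuns,cutoff screening parameters when `reports` is `NULL`.
#' @return list with `results` (list of [ModelResult-class]), `table`
#'   (data.frame of metrics per set x method x target x split), and
#'   `featureCounts` (named integer vector per target and set).
#' @export
runAblation <- function(ft, reports = NULL,
                        targets = c("grain_number", "grain_weight"),
                        methods = yieldMethods(), seed = 1L,
                        applyOCSVM = TRUE, trainFraction = 0.7,
                        nRuns = 100L, cutoff = 80L) {
  grpAll <- featureGroups(ft)
  missing <- setdiff(c("VI", "TI", "CC", "CHM", "LODGING"), grpAll)
  if (length(missing))
    stop("feature table lacks group(s): ", paste(missing, collapse = ", "))
  if (is.null(reports)) {
    reports <- lapply(targets, function(tg)
      screenFeatures(ft, tg, nRuns = nRuns, cutoff = cutoff,
                     seed = derivedSeed(seed, match(tg, targets))))
    names(reports) <- targets
  }
  cd <- SummarizedExperiment::colData(ft)
  results <- list()
  counts <- integer(0)
  for (tg in targets) {
    keep <- keptForTarget(ft, reports[[tg]])
    X <- t(featureMatrix(ft)[keep, , drop = FALSE])
    y <- cd[[tg]]
    ok <- stats::complete.cases(X) & !is.na(y)
    X <- X[ok, , drop = FALSE]; y <- y[ok]
    ids <- colnames(ft)[ok]
    if (applyOCSVM) {
      inl <- ocsvmFilter(X)
      X <- X[inl, , drop = FALSE]; y <- y[inl]; ids <- ids[inl]
    }
    sp <- splitData(nrow(X), trainFraction, seed = derivedSeed(seed, 41L))
    grpKeep <- grpAll[match(colnames(X), rownames(ft))]
    for (setName in names(ablationPlan())) {
      cols <- grpKeep %in% ablationPlan()[[setName]]
      counts[paste(tg, setName, sep = "|")] <- sum(cols)
      for (mth in methods) {
        res <- fitPredict(mth,
                          X[sp$train, cols, drop = FALSE], y[sp$train],
                          X[sp$validation, cols, drop = FALSE],
                          y[sp$validation],
                          seed = derivedSeed(seed, 57L),
                          featureSet = setName, target = tg,
                          trainIds = ids[sp$train],
                          valIds = ids[sp$validation])
        results[[length(results) + 1L]] <- res
      }
    }
  }
  list(results = results, table = resultsTable(results),
       featureCounts = counts)
}

#' Summarize model results as a data.frame
#'
#' @param results list of [ModelResult-class].
#' @return data.frame with one row per result and split: `featureSet`,
#'   `method`, `target`, `split`, `r2`, `rmse`, `rrmse`.
#' @export
resultsTable <- function(results) {
  if (!length(results)) stop("no results")
  do.call(rbind, lapply(results, function(r) {
    data.frame(featureSet = r@featureSet, method = r@method,
               target = r@target,
               split = c("train", "validation"),
               r2 = c(r@train[["r2"]], r@validation[["r2"]]),
               rmse = c(r@train[["rmse"]], r@validation[["rmse"]]),
               rrmse = c(r@train[["rrmse"]], r@validation[["rrmse"]]),
               stringsAsFactors = FALSE)
  }))
}

#' Acquisition-date sweep
#'
#' Extracts features and fits every method for every date, using all
#' available features per date (vegetation block, texture on the
#' requested bands, canopy cover, crop height, lodging — no screening),
#' and reports per-date validation metrics together with the best date
#' per target (highest validation R2 averaged over methods).
#'
#' @param scenes named list of [SceneStack-class] (names = days), >= 2
#'   dates; the first is the bare-ground reference.
#' @param plots plot table with ground truth attached.
#' @param targets,methods as in [runAblation()].
#' @param seed integer seed (same split for every date).
#' @param textureBands texture bands per date (default all three,
#'   giving the full per-date inventory).
#' @param config a [glcmConfig()].
#' @param applyOCSVM logical; clean each date's feature matrix with the
#'   one-class SVM before splitting (heavy-tailed texture statistics
#'   otherwise destabilize the linear fits on single dates).
#' @return list with `table` (date x method x target validation metrics)
#'   and `bestDate` (named numeric per target).
#' @export
runDateSweep <- function(scenes, plots,
                         targets = c("grain_number", "grain_weight"),
                         methods = yieldMethods(), seed = 1L,
                         textureBands = c("R", "G", "B"),
                         config = glcmConfig(), applyOCSVM = TRUE) {
  if (length(scenes) < 2L) stop("need at least 2 dates")
  days <- as.integer(names(scenes))
  if (any(is.na(days))) stop("scenes must be named by day")
  dem <- bareDEM(scenes[[1L]], plots)
  rows <- list()
  for (k in seq_along(scenes)) {
    ft <- extractPlotFeatures(scenes[[k]], plots, dem,
                              textureBands = textureBands, config = config)
    X <- t(featureMatrix(ft))
    cd <- SummarizedExperiment::colData(ft)
    for (tg in targets) {
      y <- cd[[tg]]
      ok <- stats::complete.cases(X) & !is.na(y)
      Xo <- X[ok, , drop = FALSE]; yo <- y[ok]
      if (applyOCSVM) {
        inl <- ocsvmFilter(Xo)
        Xo <- Xo[inl, , drop = FALSE]; yo <- yo[inl]
      }
      sp <- splitData(nrow(Xo), seed = derivedSeed(seed, 41L))
      for (mth in methods) {
        res <- fitPredict(mth, Xo[sp$train, , drop = FALSE], yo[sp$train],
                          Xo[sp$validation, , drop = FALSE],
                          yo[sp$validation],
                          seed = derivedSeed(seed, 57L),
                          featureSet = "all", target = tg)
        rows[[length(rows) + 1L]] <- data.frame(
          date = days[k], method = mth, target = tg,
          r2 = res@validation[["r2"]],
          rmse = res@validation[["rmse"]],
          rrmse = res@validation[["rrmse"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  best <- vapply(targets, function(tg) {
    sub <- tab[tab$target == tg, ]
    agg <- tapply(sub$r2, sub$date, mean)
    as.numeric(names(agg)[which.max(agg)])
  }, numeric(1))
  list(table = tab, bestDate = best)
}

#' Write machine- and human-readable result reports
#'
#' Writes `results.csv` (one row per feature set, method, target and
#' split) and `summary.json` (the ladder pivoted in the layout of the
#' published accuracy tables, plus any sweep curve supplied). Re-running
#' with identical inputs reproduces the files byte for byte.
#'
#' @param table results data.frame from [runAblation()]/[resultsTable()].
#' @param outdir output directory (created if needed).
#' @param sweep optional sweep result from [runDateSweep()].
#' @return invisibly, the paths written.
#' @export
writeReport <- function(table, outdir, sweep = NULL) {
  if (missing(table) || is.null(table) || !nrow(table))
    stop("no results to report")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(outdir, "results.csv")
  write.csv(table[order(table$target, table$featureSet, table$method,
                        table$split), ],
            csv, row.names = FALSE)
  summary <- list(ladder = split(table, table$target))
  if (!is.null(sweep)) {
    summary$sweep <- sweep$table
    summary$bestDate <- as.list(sweep$bestDate)
  }
  js <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns")
  invisible(c(csv = csv, json = js))
}
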