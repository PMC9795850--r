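## Crop height: Otsu bare-ground estimation, CHM = DSM - DEM, plot height.

#' Otsu threshold of a numeric sample
#'
#' Quantizes the values to `levels` equal-width bins over their range and
#' returns the threshold maximizing the between-class variance, together
#' with the class means. Near-constant samples (range below `tol`) are
#' degenerate: no threshold exists and both class means equal the sample
#' mean.
#'
#' @param x numeric values.
#' @param levels number of histogram bins (default 256).
#' @param tol range below which the sample is treated as constant.
#' @return list with `threshold` (in the units of `x`; `NA` when
#'   degenerate), `lowerMean`, `upperMean`, and logical `degenerate`.
#' @export
otsuThreshold <- function(x, levels = 256L, tol = 1e-8) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty sample")
  lo <- min(x); hi <- max(x)
  if (hi - lo < tol)
    return(list(threshold = NA_real_, lowerMean = mean(x),
                upperMean = mean(x), degenerate = TRUE))
  q <- pmin(floor((x - lo) / (hi - lo) * levels), levels - 1L)
  h <- tabulate(q + 1L, nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(levels) - 1L))
  muT <- mu[levels]
  ## between-class variance for threshold after bin t (t = 1..levels-1)
  w0 <- omega[-levels]
  m0 <- mu[-levels]
  valid <- w0 > 0 & w0 < 1
  sigmaB <- rep(-Inf, levels - 1L)
  sigmaB[valid] <- (muT * w0[valid] - m0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  t <- which.max(sigmaB) # bins 0..t-1 are the lower class
  thr <- lo + t * (hi - lo) / levels
  list(threshold = thr,
       lowerMean = mean(x[x < thr]),
       upperMean = mean(x[x >= thr]),
       degenerate = FALSE)
}

#' Bare-ground elevation of a plot from the pre-emergence scene
#'
#' Splits the plot's DSM heights into two classes with the Otsu threshold
#' and returns the mean of the lower class as the bare-ground elevation
#' (one constant per plot). When the heights are near-constant — the usual
#' case on a truly pre-emergence date — the plot mean is returned.
#'
#' @param earlyScene the first-date [SceneStack-class] (pre-emergence).
#' @param plot single-row plot record.
#' @param levels Otsu histogram bins.
#' @return numeric bare-ground elevation (m).
#' @export
estimateBareDEM <- function(earlyScene, plot, levels = 256L) {
  blk <- clipPlot(earlyScene, plot)
  if (!length(blk$dsm)) stop("empty plot")
  o <- otsuThreshold(as.numeric(blk$dsm), levels)
  if (o$degenerate) mean(blk$dsm) else o$lowerMean
}

#' Crop height model from DSM and bare-ground DEM
#'
#' `CHM = DSM - DEM` pixel-wise, with negative values clipped to zero
#' (heights below bare ground are physically impossible). The DEM may be
#' a per-plot constant or a full grid.
#'
#' @param scene a [SceneStack-class], or a DSM matrix.
#' @param dem scalar or matrix of bare-ground elevations (m).
#' @return matrix of crop heights (m, >= 0).
#' @export
computeCHM <- function(scene, dem) {
  dsm <- if (is(scene, "SceneStack")) scene@dsm else scene
  pmax(dsm - dem, 0)
}

#' Plot-level crop height
#'
#' Mean CHM over canopy pixels (mask from [canopyCover()]); falls back to
#' the whole-plot mean when coverage is zero, flagged in the result.
#'
#' @param chm crop-height grid of the plot (m).
#' @param canopyMask logical grid of the same shape.
#' @param statistic `"mean"` (default) or `"p90"` (90th percentile).
#' @return list with `height` (m) and `canopyMasked` (logical flag;
#'   `FALSE` means the whole-plot fallback was used).
#' @export
plotHeight <- function(chm, canopyMask, statistic = c("mean", "p90")) {
  statistic <- match.arg(statistic)
  vals <- if (any(canopyMask)) chm[canopyMask] else as.numeric(chm)
  h <- switch(statistic,
              mean = mean(vals),
              p90 = as.numeric(quantile(vals, 0.9, names = FALSE)))
  list(height = h, canopyMasked = any(canopyMask))
}

#' Agreement between estimated and observed heights
#'
#' Ordinary least-squares agreement metrics between paired estimates and
#' observations: squared Pearson correlation (the OLS R-squared) and the
#' root mean square difference.
#'
#' @param estimates,observations paired numeric vectors, length >= 3.
#' @return list with `r2` and `rmse` (same units as the inputs).
#' @export
validateHeights <- function(estimates, observations) {
  if (length(estimates) != length(observations))
    stop("estimates and observations differ in length")
  if (length(estimates) < 3L) stop("need at least 3 pairs")
  r2 <- if (sd(estimates) == 0 || sd(observations) == 0) {
    if (all(estimates - observations ==
              (estimates - observations)[1])) 1 else 0
  } else cor(estimates, observations)^2
  list(r2 = r2, rmse = sqrt(mean((estimates - observations)^2)))
}
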