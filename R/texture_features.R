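## Gray-level co-occurrence matrix (GLCM) texture features.
##
## Nine GLCM metrics are computed in 3x3 sliding windows over each
## quantized band and summarized per plot by five statistics (mean, min,
## max, SD, CV), giving 45 variables per band and 135 for three bands.
## The per-window metrics run through compiled code (src/glcm.cpp); a
## pure-R path ([glcm()] + [glcmMetrics()]) with identical definitions
## serves single matrices and arbitrary offsets.

#' GLCM configuration
#'
#' @param levels gray-level count after quantization (default 32; >= 2).
#' @param window processing window as `c(rows, cols)`, odd-sized
#'   (default `c(3, 3)`).
#' @param offsets integer matrix of `(dRow, dCol)` displacements; default
#'   distance 1 at 0, 45, 90 and 135 degrees, averaged.
#' @param symmetric logical, count each pair in both directions
#'   (default `TRUE`).
#' @return a named list of class `GLCMConfig`.
#' @export
glcmConfig <- function(levels = 32L, window = c(3L, 3L),
                       offsets = rbind(c(0L, 1L), c(-1L, 1L),
                                       c(-1L, 0L), c(-1L, -1L)),
                       symmetric = TRUE) {
  if (levels < 2L) stop("levels must be >= 2")
  if (any(window %% 2L == 0L)) stop("window must be odd-sized")
  if (!nrow(offsets)) stop("offsets must be non-empty")
  structure(list(levels = as.integer(levels), window = as.integer(window),
                 offsets = apply(offsets, 2L, as.integer),
                 symmetric = symmetric),
            class = "GLCMConfig")
}

#' Quantize a DN grid to integer gray levels
#'
#' Linear binning of the grid's DN range to `{0, ..., levels - 1}`;
#' constant grids map entirely to level 0.
#'
#' @param x numeric grid.
#' @param levels number of gray levels (>= 2).
#' @return integer matrix of levels.
#' @examples
#' quantizeGrid(matrix(c(0, 85, 170, 255), 2), 4L)
#' @export
quantizeGrid <- function(x, levels = 32L) {
  if (levels < 2L) stop("levels must be >= 2")
  lo <- min(x); hi <- max(x)
  q <- if (hi > lo) pmin(floor((x - lo) / (hi - lo) * levels),
                         levels - 1L) else x * 0
  matrix(as.integer(q), nrow(x), ncol(x))
}

#' Co-occurrence matrix of one window
#'
#' Counts level pairs at the configured offsets over a quantized grid and
#' normalizes to a probability matrix. With `symmetric = TRUE` every pair
#' is counted in both directions, so the matrix is symmetric and sums to
#' one.
#'
#' @param window integer matrix of quantized levels.
#' @param config a [glcmConfig()] (its `window` slot is ignored here; the
#'   whole input grid is treated as one window).
#' @return `levels x levels` normalized co-occurrence matrix.
#' @export
glcm <- function(window, config = glcmConfig()) {
  L <- config$levels
  off <- config$offsets
  if (is.null(dim(off))) off <- matrix(off, ncol = 2L)
  nr <- nrow(window); nc <- ncol(window)
  if (any(abs(off[, 1]) >= nr) || any(abs(off[, 2]) >= nc))
    stop("window smaller than offset reach")
  p <- matrix(0, L, L)
  for (m in seq_len(nrow(off))) {
    dr <- off[m, 1]; dc <- off[m, 2]
    rs <- max(1L, 1L - dr):min(nr, nr - dr)
    cs <- max(1L, 1L - dc):min(nc, nc - dc)
    a <- window[rs, cs, drop = FALSE]
    b <- window[rs + dr, cs + dc, drop = FALSE]
    for (k in seq_along(a)) {
      p[a[k] + 1L, b[k] + 1L] <- p[a[k] + 1L, b[k] + 1L] + 1
      if (config$symmetric)
        p[b[k] + 1L, a[k] + 1L] <- p[b[k] + 1L, a[k] + 1L] + 1
    }
  }
  if (sum(p) == 0) stop("window contains no valid offset pair")
  p / sum(p)
}

#' Names of the nine GLCM metrics
#' @return character vector in stable order.
#' @export
glcmMetricNames <- function() {
  c("mean", "variance", "homogeneity", "contrast", "dissimilarity",
    "entropy", "energy", "correlation", "autocorrelation")
}

#' Nine GLCM metrics of a normalized co-occurrence matrix
#'
#' With `p(i, j)` the normalized co-occurrence probabilities over levels
#' `i, j = 0..L-1`: mean `mu = sum(i * p)`, variance
#' `sum((i - mu)^2 * p)`, homogeneity `sum(p / (1 + (i - j)^2))`,
#' contrast `sum((i - j)^2 * p)`, dissimilarity `sum(|i - j| * p)`,
#' entropy `-sum(p * log(p))` (with `0 log 0 := 0`), energy `sum(p^2)`
#' (angular second moment), correlation
#' `sum((i - mu) (j - mu) p) / variance` (defined as 1 when the variance
#' vanishes), and autocorrelation `sum(i * j * p)`.
#'
#' @param p normalized co-occurrence matrix (sums to 1).
#' @return named numeric vector of the nine metrics.
#' @export
glcmMetrics <- function(p) {
  if (abs(sum(p) - 1) > 1e-8)
    stop("co-occurrence matrix is not normalized")
  L <- nrow(p)
  i <- matrix(0:(L - 1L), L, L)
  j <- t(i)
  mu <- sum(i * p)
  v <- sum((i - mu)^2 * p)
  plog <- ifelse(p > 0, p * log(p), 0)
  c(mean = mu,
    variance = v,
    homogeneity = sum(p / (1 + (i - j)^2)),
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    entropy = -sum(plog),
    energy = sum(p^2),
    correlation = if (v < 1e-15) 1 else sum((i - mu) * (j - mu) * p) / v,
    autocorrelation = sum(i * j * p))
}

#' Names of the plot-level texture statistics
#' @return character vector: mean, min, max, sd, cv.
#' @export
textureStatNames <- function() c("mean", "min", "max", "sd", "cv")

#' Plot-level GLCM texture feature block
#'
#' Quantizes each requested band of the plot, computes the nine GLCM
#' metrics in every sliding window fully inside the plot (no padding),
#' and aggregates each metric over windows with five statistics (mean,
#' min, max, SD, CV = SD/mean, missing when the mean is zero): 45
#' features per band, 135 for all three. Feature names follow
#' `<band>_<metric>_<stat>`.
#'
#' @param block clipped plot block ([clipPlot()] output) or `R`/`G`/`B`
#'   list.
#' @param bands character subset of `c("R", "G", "B")`.
#' @param config a [glcmConfig()].
#' @return named numeric vector of `45 * length(bands)` features.
#' @export
plotTextureFeatures <- function(block, bands = c("R", "G", "B"),
                                config = glcmConfig()) {
  bl <- asBands(block)
  bands <- match.arg(bands, c("R", "G", "B"), several.ok = TRUE)
  w <- config$window
  out <- numeric(0)
  for (bn in bands) {
    grid <- bl[[bn]]
    if (nrow(grid) < w[1] || ncol(grid) < w[2])
      stop("plot smaller than the ", w[1], "x", w[2], " processing window")
    q <- quantizeGrid(grid, config$levels)
    met <- .glcmWindowMetrics(q, config$levels, w[1], w[2],
                              rbind(config$offsets))
    colnames(met) <- glcmMetricNames()
    stats <- vapply(glcmMetricNames(), function(mn) {
      v <- met[, mn]
      m <- mean(v); s <- sd(v)
      if (length(v) == 1L) s <- 0
      c(mean = m, min = min(v), max = max(v), sd = s,
        cv = if (m == 0) NA_real_ else s / m)
    }, numeric(5))
    vals <- as.numeric(stats)
    names(vals) <- paste(bn, rep(glcmMetricNames(), each = 5L),
                         rep(textureStatNames(), times = 9L), sep = "_")
    out <- c(out, vals)
  }
  out
}
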