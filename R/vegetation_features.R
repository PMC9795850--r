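## RGB vegetation indices and excess-green canopy cover.
##
## Fifteen named visible-band indices plus the six normalized bands and
## the three raw band means form the 24-variable vegetation block. Raw DN
## symbols (capital R, G, B) and chromatic coordinates (lower-case r, g,
## b) are deliberately kept distinct: ratio indices written with capitals
## are evaluated on raw DN, the rest on chromatic coordinates.

#' Names of the vegetation-block features
#'
#' @return character vector of the 24 feature names: 15 named indices,
#'   the 6 normalized bands and the 3 raw band means, in stable order.
#' @export
viFeatureNames <- function() {
  c("CIVE", "COMB1", "COMB2", "ExG", "EXGR", "GRI", "GRVI", "MGRVI",
    "PPRb", "RGBVI", "SAVI", "VARI", "VDVI", "VEG", "WI",
    "Rn", "Gn", "Bn", "r", "g", "b", "R", "G", "B")
}

viIndexNames <- function() viFeatureNames()[1:15]

asBands <- function(block) {
  if (is.list(block) && !is.null(block$rgb)) {
    list(R = block$rgb[, , 1], G = block$rgb[, , 2], B = block$rgb[, , 3])
  } else if (is.list(block) && all(c("R", "G", "B") %in% names(block))) {
    block[c("R", "G", "B")]
  } else stop("block must contain an rgb array or R, G, B grids")
}

#' Normalize bands and derive chromatic coordinates
#'
#' Computes normalized bands `Rn = R/max(R)` etc. against the observed
#' band maxima, and chromatic coordinates `r = Rn/(Rn+Gn+Bn)` (likewise
#' g, b), which sum to one on every pixel with non-zero DN sum. The
#' maxima are per scene, not per plot: pass the scene-wide maxima via
#' `maxima` when normalizing a clipped plot block (plot-level extraction
#' does this automatically), otherwise the block's own maxima are used.
#' All-zero (black) pixels are flagged invalid and excluded from plot
#' aggregation.
#'
#' @param block a clipped plot block ([clipPlot()] output) or a list with
#'   `R`, `G`, `B` DN grids.
#' @param maxima optional numeric length-3 `(Rmax, Gmax, Bmax)` observed
#'   over the whole scene.
#' @return list with raw bands, maxima `Rmax`, `Gmax`, `Bmax`, normalized
#'   `Rn`, `Gn`, `Bn`, chromatic `r`, `g`, `b`, and logical `valid`.
#' @export
normalizeBands <- function(block, maxima = NULL) {
  b <- asBands(block)
  if (!length(b$R)) stop("empty block")
  if (is.null(maxima)) maxima <- c(max(b$R), max(b$G), max(b$B))
  Rmax <- maxima[[1]]; Gmax <- maxima[[2]]; Bmax <- maxima[[3]]
  if (Rmax <= 0 && Gmax <= 0 && Bmax <= 0)
    stop("all-black plot: no vegetation signal")
  Rn <- if (Rmax > 0) b$R / Rmax else b$R * 0
  Gn <- if (Gmax > 0) b$G / Gmax else b$G * 0
  Bn <- if (Bmax > 0) b$B / Bmax else b$B * 0
  s <- Rn + Gn + Bn
  valid <- s > 0
  r <- ifelse(valid, Rn / s, NA_real_)
  g <- ifelse(valid, Gn / s, NA_real_)
  bb <- ifelse(valid, Bn / s, NA_real_)
  list(R = b$R, G = b$G, B = b$B, Rmax = Rmax, Gmax = Gmax, Bmax = Bmax,
       Rn = Rn, Gn = Gn, Bn = Bn, r = r, g = g, b = bb, valid = valid)
}

## Each index as printed; undefined pixels (zero denominators) become NA
## and are excluded from plot means.
viRegistry <- list(
  ExG   = function(x) 2 * x$g - x$r - x$b,
  EXGR  = function(x) (2 * x$g - x$r - x$b) - 1.4 * x$r - x$g,
  CIVE  = function(x) 18.78745 + 0.44 * x$r - 0.88 * x$g + 0.385 * x$b,
  VEG   = function(x) {
    a <- 0.667
    den <- x$r^a * x$b^(1 - a)
    ifelse(is.na(den) | den == 0, NA_real_, x$g / den)
  },
  WI    = function(x) {
    den <- abs(x$r - x$g)
    ifelse(is.na(den) | den == 0, NA_real_, (x$g - x$b) / den)
  },
  COMB1 = function(x) {
    exg <- viRegistry$ExG(x)
    0.25 * exg + 0.3 * viRegistry$EXGR(x) + 0.33 * viRegistry$CIVE(x) +
      0.12 * viRegistry$VEG(x)
  },
  COMB2 = function(x) {
    0.36 * viRegistry$ExG(x) + 0.47 * viRegistry$CIVE(x) +
      0.17 * viRegistry$VEG(x)
  },
  GRI   = function(x) ifelse(x$R == 0, NA_real_, x$G / x$R),
  GRVI  = function(x) ifelse(x$G + x$R == 0, NA_real_,
                             (x$G - x$R) / (x$G + x$R)),
  MGRVI = function(x) ifelse(x$G^2 + x$R^2 == 0, NA_real_,
                             (x$G^2 - x$R^2) / (x$G^2 + x$R^2)),
  PPRb  = function(x) ifelse(x$G + x$B == 0, NA_real_,
                             (x$G - x$B) / (x$G + x$B)),
  RGBVI = function(x) {
    den <- x$G^2 + x$R * x$B
    ifelse(den == 0, NA_real_, (x$G^2 - x$R * x$B) / den)
  },
  SAVI  = function(x) 1.5 * (x$G - x$R) / (x$G + x$R + 0.5),
  VARI  = function(x) {
    den <- x$G + x$R - x$B
    ifelse(den == 0, NA_real_, (x$G - x$R) / den)
  },
  VDVI  = function(x) ifelse(2 * x$G + x$R + x$B == 0, NA_real_,
                             (2 * x$G - x$R - x$B) / (2 * x$G + x$R + x$B))
)

#' Evaluate one vegetation index pixel-wise
#'
#' @param name one of the 15 index names (see [viFeatureNames()]).
#' @param bands output of [normalizeBands()].
#' @return numeric grid of per-pixel index values; undefined pixels
#'   (zero denominators, invalid pixels) are `NA`.
#' @examples
#' b <- normalizeBands(list(R = matrix(100), G = matrix(200),
#'                          B = matrix(50)))
#' computeIndex("ExG", b) # 0.7143
#' @export
computeIndex <- function(name, bands) {
  if (!name %in% viIndexNames())
    stop("unknown index '", name, "'; valid names: ",
         paste(viIndexNames(), collapse = ", "))
  v <- viRegistry[[name]](bands)
  v[!bands$valid] <- NA_real_
  v
}

#' Plot-level vegetation feature block
#'
#' Means over all valid plot pixels of the 15 indices, the 6 normalized
#' bands and the 3 raw bands — 24 values in the stable order of
#' [viFeatureNames()]. By default the mean runs over every valid pixel in
#' the plot (soil included); set `canopyMaskOnly = TRUE` to restrict to
#' the excess-green canopy mask.
#'
#' @param block clipped plot block or `R`/`G`/`B` list.
#' @param maxima optional scene-wide band maxima (see [normalizeBands()]).
#' @param canopyMaskOnly logical; restrict means to canopy pixels.
#' @param threshold EGI threshold used when `canopyMaskOnly` is `TRUE`.
#' @return named numeric vector of length 24.
#' @export
plotVIFeatures <- function(block, maxima = NULL, canopyMaskOnly = FALSE,
                           threshold = 0.05) {
  bands <- normalizeBands(block, maxima)
  keep <- bands$valid
  if (canopyMaskOnly) {
    cc <- canopyCover(block, threshold)
    keep <- keep & cc$mask
  }
  if (!any(keep)) stop("no valid pixels in plot")
  vals <- vapply(viIndexNames(), function(nm) {
    v <- computeIndex(nm, bands)
    mean(v[keep], na.rm = TRUE)
  }, numeric(1))
  extra <- c(Rn = mean(bands$Rn[keep]), Gn = mean(bands$Gn[keep]),
             Bn = mean(bands$Bn[keep]), r = mean(bands$r[keep]),
             g = mean(bands$g[keep]), b = mean(bands$b[keep]),
             R = mean(bands$R[keep]), G = mean(bands$G[keep]),
             B = mean(bands$B[keep]))
  out <- c(vals, extra)[viFeatureNames()]
  out
}

#' Excess-green canopy cover of a plot
#'
#' Binarizes the plot with the excess green index `EGI = (2G - R - B)/G`
#' at the given threshold (default 0.05): pixels with `EGI > threshold`
#' are canopy, the rest (including `G = 0` pixels) soil. Returns the
#' canopy pixel fraction and the binary mask for downstream masking.
#'
#' @param block clipped plot block or `R`/`G`/`B` list.
#' @param threshold EGI threshold (default 0.05).
#' @return list with `fraction` in `[0, 1]` and logical `mask`.
#' @export
canopyCover <- function(block, threshold = 0.05) {
  b <- asBands(block)
  if (!length(b$G)) stop("empty block")
  egi <- ifelse(b$G > 0, (2 * b$G - b$R - b$B) / b$G, -Inf)
  mask <- egi > threshold
  list(fraction = mean(mask), mask = mask)
}
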