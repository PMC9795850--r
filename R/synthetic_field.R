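## Synthetic field generator: layout, ground truth, and scene rendering.
## Emulates a large single-season soybean germplasm trial so that every
## downstream stage of the pipeline can be exercised without field data.

#' Generate the plot layout of a field trial
#'
#' Lays the plots of a [fieldDesign()] on a near-square axis-aligned grid,
#' separated by furrow gaps. The layout is purely deterministic — it
#' depends only on the design, never on a random seed. Control plots are
#' spread evenly through the field (they double as the crop-height
#' validation set), cycling through 30 control cultivar identifiers.
#'
#' @param design a [FieldDesign-class].
#' @return data.frame with one row per plot: `plot_id`, `cultivar_id`,
#'   `is_control`, rectangle corners `xmin`, `ymin`, `xmax`, `ymax` (map
#'   metres; the first plot's corner is at the origin), and empty ground
#'   columns `lodging`, `grain_number`, `grain_weight`.
#' @examples
#' layout <- generateLayout(fieldDesign(10, 2))
#' nrow(layout)
#' @export
generateLayout <- function(design) {
  stopifnot(is(design, "FieldDesign"))
  validObject(design)
  n <- nPlots(design)
  xstep <- design@plotWidth + design@furrowGap
  ystep <- design@plotLength + design@furrowGap
  ncols <- max(1L, as.integer(round(sqrt(n * ystep / xstep))))
  idx <- seq_len(n) - 1L
  col <- idx %% ncols
  row <- idx %/% ncols
  xmin <- col * xstep
  ymin <- row * ystep
  ctrl <- logical(n)
  if (design@nControlPlots > 0L) {
    pick <- unique(as.integer(round(seq(1L, n,
                                        length.out = design@nControlPlots))))
    while (length(pick) < design@nControlPlots)
      pick <- union(pick, setdiff(seq_len(n), pick)[1L])
    ctrl[pick] <- TRUE
  }
  cultivar <- character(n)
  cultivar[!ctrl] <- sprintf("CV%04d", seq_len(sum(!ctrl)))
  cultivar[ctrl] <- sprintf("CTRL%02d", (seq_len(sum(ctrl)) - 1L) %% 30L + 1L)
  data.frame(
    plot_id = sprintf("P%04d", seq_len(n)),
    cultivar_id = cultivar,
    is_control = ctrl,
    xmin = xmin, ymin = ymin,
    xmax = xmin + design@plotWidth,
    ymax = ymin + design@plotLength,
    lodging = NA_integer_,
    grain_number = NA_real_,
    grain_weight = NA_real_,
    stringsAsFactors = FALSE)
}

#' Simulate per-plot ground truth
#'
#' Draws the five latent axes per plot (growth vigor, green chroma, blue
#' chroma, texture amplitude, texture granularity), derives the
#' canopy-growth and plant-height curve parameters from the growth-vigor
#' axis, assigns ordinal lodging levels (1 = all upright .. 5 = all
#' lodged) from a latent score weakly increasing with final height, and
#' generates the two yield parameters from the linear model
#' `y = a0 + a1*vigorComposite + a2*heightFinal + a3*(lodging - 1) + eps`
#' truncated at zero, where the vigor composite is the weighted sum of
#' the five axes. Fully reproducible from `seed`.
#'
#' @param layout plot table from [generateLayout()].
#' @param params a [GrowthParams-class].
#' @param seed integer seed.
#' @return data.frame with one row per plot: `plot_id`, latent axes
#'   `vigor`, `chroma`, `blue_chroma`, `struct_amp`, `struct_gran`, the
#'   composite `vigor_composite`, growth parameters `canopy_asym`,
#'   `canopy_mid`, `height_max` (m), and ground truth `lodging` (1-5),
#'   `grain_number` (seeds/plant), `grain_weight` (g/plant).
#' @seealso [canopyFractionAt()], [plantHeightAt()] for the per-date
#'   growth curves implied by the truth table.
#' @export
simulateTruth <- function(layout, params, seed = 1L) {
  stopifnot(is(params, "GrowthParams"), nrow(layout) > 0L)
  validObject(params)
  n <- nrow(layout)
  withSeed(derivedSeed(seed, 11L), {
    vigor <- rnorm(n, 0, params@vigorSd)
    chroma <- rnorm(n, 0, params@vigorSd)
    blueChroma <- rnorm(n, 0, params@vigorSd)
    structAmp <- rnorm(n, 0, params@vigorSd)
    structGran <- rnorm(n, 0, params@vigorSd)
    w <- params@vigorWeights
    vc <- w[1] * vigor + w[2] * chroma + w[3] * blueChroma +
      w[4] * structAmp + w[5] * structGran
    asym <- clamp(params@canopyAsymBase + params@canopyAsymSlope * vigor,
                  0.05, params@canopyAsymMax)
    mid <- clamp(params@canopyMidBase + params@canopyMidSlope * vigor, 15, 45)
    hmax <- pmax(0.2, params@heightMaxBase + params@heightMaxSlope * vigor +
                   rnorm(n, 0, params@heightMaxSd))
    eta <- params@lodgingSlope * as.numeric(scale(hmax)) + rnorm(n)
    if (n >= 5L) {
      cuts <- quantile(eta, cumsum(params@lodgingProbs)[1:4], names = FALSE)
      lodging <- findInterval(eta, cuts, left.open = TRUE) + 1L
    } else {
      lodging <- rep(1L, n)
    }
    a <- params@grainNumberCoef
    gn <- pmax(0, a[1] + a[2] * vc + a[3] * hmax + a[4] * (lodging - 1) +
                 rnorm(n, 0, params@grainNumberSd))
    b <- params@grainWeightCoef
    gw <- pmax(0, b[1] + b[2] * vc + b[3] * hmax + b[4] * (lodging - 1) +
                 rnorm(n, 0, params@grainWeightSd))
    data.frame(plot_id = layout$plot_id, vigor = vigor, chroma = chroma,
               blue_chroma = blueChroma, struct_amp = structAmp,
               struct_gran = structGran, vigor_composite = vc,
               canopy_asym = asym, canopy_mid = mid, height_max = hmax,
               lodging = lodging, grain_number = gn, grain_weight = gw,
               stringsAsFactors = FALSE)
  })
}

#' Canopy cover fraction of each plot at a given day
#'
#' Logistic growth `asym / (1 + exp(-rate * (day - mid)))`; non-decreasing
#' in time, so cover never exceeds its asymptote.
#'
#' @param truth truth table from [simulateTruth()].
#' @param day days after sowing.
#' @param params the [GrowthParams-class] used to simulate the truth.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
canopyFractionAt <- function(truth, day, params) {
  truth$canopy_asym * plogis(params@canopyRate * (day - truth$canopy_mid))
}

#' Mean plant height of each plot at a given day
#'
#' @inheritParams canopyFractionAt
#' @return numeric vector of heights (m).
#' @export
plantHeightAt <- function(truth, day, params) {
  truth$height_max * plogis(params@heightRate * (day - params@heightMid))
}

#' Attach simulated ground truth to a plot table
#'
#' @param layout plot table from [generateLayout()].
#' @param truth truth table from [simulateTruth()].
#' @return the layout with `lodging`, `grain_number`, `grain_weight` filled.
#' @export
attachTruth <- function(layout, truth) {
  i <- match(layout$plot_id, truth$plot_id)
  layout$lodging <- truth$lodging[i]
  layout$grain_number <- truth$grain_number[i]
  layout$grain_weight <- truth$grain_weight[i]
  layout
}

## Pixel window of a rectangle under the pixel-centre / half-open rule.
## Returns NULL when no pixel centre falls inside.
rectWindow <- function(transform, nr, nc, xmin, ymin, xmax, ymax) {
  g <- transform[["xres"]]
  eps <- 1e-9
  col0 <- ceiling((xmin - transform[["xmin"]]) / g - 0.5 - eps)
  col1 <- ceiling((xmax - transform[["xmin"]]) / g - 0.5 - eps)
  row0 <- ceiling((transform[["ymax"]] - ymax) / g - 0.5 - eps)
  row1 <- ceiling((transform[["ymax"]] - ymin) / g - 0.5 - eps)
  col0 <- max(col0, 0L); row0 <- max(row0, 0L)
  col1 <- min(col1, nc); row1 <- min(row1, nr)
  if (col1 <= col0 || row1 <= row0) return(NULL)
  list(rows = (row0 + 1L):row1, cols = (col0 + 1L):col1)
}

#' Render the field scene for one acquisition date
#'
#' Builds the registered RGB + DSM raster pair for one date. Every plot
#' receives a spatially coherent canopy blob whose pixel count matches the
#' plot's canopy fraction for that date (to within rounding); canopy
#' pixels are green-dominant (excess green index > 0.05 by construction)
#' and soil pixels are soil-toned (EGI <= 0.05), with soil darker than
#' canopy in all three bands. The DSM is the base elevation plus static
#' micro-relief, plus the plot's plant height over canopy pixels, plus
#' per-date measurement noise. The first scheduled date is pre-emergence
#' (near-zero canopy) so it can serve as the bare-ground reference.
#'
#' @param layout plot table from [generateLayout()].
#' @param truth truth table from [simulateTruth()].
#' @param day acquisition day; must be in `design@dates`.
#' @param design the [FieldDesign-class].
#' @param params the [GrowthParams-class].
#' @param seed master seed. Terrain micro-relief is derived from `seed`
#'   alone (identical across dates); pixel noise additionally from `day`.
#' @return a [SceneStack-class].
#' @export
renderScene <- function(layout, truth, day, design, params, seed = 1L) {
  stopifnot(is(design, "FieldDesign"), is(params, "GrowthParams"))
  if (!day %in% design@dates)
    stop("day ", day, " is not in the acquisition schedule")
  g <- design@gsd
  xmin <- -design@margin
  ymin <- -design@margin
  xmax <- max(layout$xmax) + design@margin
  ymax <- max(layout$ymax) + design@margin
  nc <- as.integer(ceiling((xmax - xmin) / g))
  nr <- as.integer(ceiling((ymax - ymin) / g))
  transform <- c(xres = g, yres = -g, xmin = xmin, ymax = ymax)

  soil <- params@soilRGB
  R <- matrix(soil[1], nr, nc); G <- matrix(soil[2], nr, nc)
  B <- matrix(soil[3], nr, nc)
  ## static terrain, shared across dates
  dsm <- withSeed(derivedSeed(seed, 101L),
                  matrix(design@baseElevation +
                           rnorm(nr * nc, 0, params@terrainSd), nr, nc))

  frac <- canopyFractionAt(truth, day, params)
  hgt <- plantHeightAt(truth, day, params)
  ## cultivar chroma and canopy-structure expression develop toward
  ## flowering: early canopies look alike, flowering canopies do not
  stage <- plogis(params@stageRate * (day - params@stageMid))
  withSeed(derivedSeed(seed, 1000L + day), {
    ## soil colour jitter over the whole scene
    R <- R + rnorm(nr * nc, 0, params@soilJitterSd)
    G <- G + rnorm(nr * nc, 0, params@soilJitterSd)
    B <- B + rnorm(nr * nc, 0, params@soilJitterSd)
    for (i in seq_len(nrow(layout))) {
      w <- rectWindow(transform, nr, nc, layout$xmin[i], layout$ymin[i],
                      layout$xmax[i], layout$ymax[i])
      if (is.null(w)) next
      ph <- length(w$rows); pw <- length(w$cols)
      npix <- ph * pw
      k <- round(frac[i] * npix)
      if (k < 1) next
      ## coherent blob: elliptical distance + smooth noise, k nearest pixels
      cr <- (ph + 1) / 2 + rnorm(1, 0, 0.05 * ph)
      cc <- (pw + 1) / 2 + rnorm(1, 0, 0.05 * pw)
      dr <- (seq_len(ph) - cr) / (ph / 2)
      dc <- (seq_len(pw) - cc) / (pw / 2)
      d <- sqrt(outer(dr^2, dc^2, "+")) + 0.35 * smoothNoise(ph, pw)
      ## plot corners stay bare (row ends abut the furrow): cover is
      ## capped accordingly
      if (ph >= 3L && pw >= 3L) {
        d[c(1:3, ph - 2:0), c(1:3, pw - 2:0)] <- Inf
      }
      mask <- matrix(FALSE, ph, pw)
      mask[order(d)[seq_len(min(k, sum(is.finite(d))))]] <- TRUE
      nk <- sum(mask)
      v <- truth$vigor[i]
      ## canopy texture: one common field per plot mixing a smooth
      ## component (leaf clumps) with per-pixel speckle; amplitude and
      ## granularity follow the plot's structure axes
      sdc <- clamp(params@structAmpBase + stage *
                     params@structAmpSlope * truth$struct_amp[i], 1.5, 12)
      alpha <- plogis(params@granularitySlope * truth$struct_gran[i])
      S <- smoothNoise(ph, pw)
      S <- S / max(sd(S), 1e-6)
      J <- sqrt(alpha) * S + sqrt(1 - alpha) * matrix(rnorm(npix), ph, pw)
      can <- params@canopyRGB +
        stage * c(params@chromaShiftR * truth$chroma[i],
                  params@chromaShiftG * truth$chroma[i],
                  params@blueShiftB * truth$blue_chroma[i]) +
        c(0, params@canopyShiftG * v, 0) +
        rnorm(3, 0, params@plotColorSd)
      subR <- R[w$rows, w$cols]; subG <- G[w$rows, w$cols]
      subB <- B[w$rows, w$cols]
      ## per-plot soil tint (moisture/background): within a plot the
      ## tilled soil is uniform, one integer DN per band
      tint <- rnorm(3, 0, params@soilTintSd)
      soilDN <- round(params@soilRGB + tint)
      subR[!mask] <- soilDN[1]
      subG[!mask] <- soilDN[2]
      subB[!mask] <- soilDN[3]
      ## shaded rim: soil pixels bordering the canopy blob sit between
      ## soil and canopy brightness; rim strength follows the texture
      ## amplitude axis (denser canopies cast harder edge shadow). The
      ## bare corner patches are never rimmed.
      rim <- (rbind(mask[-1, , drop = FALSE], FALSE) |
                rbind(FALSE, mask[-ph, , drop = FALSE]) |
                cbind(mask[, -1, drop = FALSE], FALSE) |
                cbind(FALSE, mask[, -pw, drop = FALSE])) & !mask
      if (ph >= 3L && pw >= 3L)
        rim[c(1:3, ph - 2:0), c(1:3, pw - 2:0)] <- FALSE
      rimF <- 0.5 * plogis(0.8 * truth$struct_amp[i])
      nrim <- sum(rim)
      if (nrim) {
        subR[rim] <- soilDN[1] + rimF * (can[1] - soilDN[1]) +
          rnorm(nrim)
        subG[rim] <- soilDN[2] + rimF * (can[2] - soilDN[2]) +
          rnorm(nrim)
        subB[rim] <- soilDN[3] + rimF * (can[3] - soilDN[3]) +
          rnorm(nrim)
      }
      bs <- params@bandScale
      subR[mask] <- can[1] + bs[1] * sdc * J[mask] + rnorm(nk, 0, 0.5)
      subG[mask] <- can[2] + bs[2] * sdc * J[mask] + rnorm(nk, 0, 0.5)
      subB[mask] <- can[3] + bs[3] * sdc * J[mask] + rnorm(nk, 0, 0.5)
      ## canopy stays brighter than the plot's soil in every band so the
      ## darkest quantization level is always bare soil
      subR[mask] <- pmax(subR[mask], soilDN[1] + 8)
      subG[mask] <- pmax(subG[mask], soilDN[2] + 8)
      subB[mask] <- pmax(subB[mask], soilDN[3] + 8)
      subR <- round(clamp(subR, 0, 255)); subG <- round(clamp(subG, 0, 255))
      subB <- round(clamp(subB, 0, 255))
      ## enforce the EGI contract exactly: canopy > 0.05, soil <= 0.05
      lim <- (subR + subB) / 1.95
      subG[mask] <- pmax(subG[mask], floor(lim[mask]) + 1)
      subG[!mask] <- pmin(subG[!mask], floor(lim[!mask]))
      subG <- clamp(subG, 0, 255)
      R[w$rows, w$cols] <- subR; G[w$rows, w$cols] <- subG
      B[w$rows, w$cols] <- subB
      subD <- dsm[w$rows, w$cols]
      subD[mask] <- subD[mask] + hgt[i] +
        rnorm(nk, 0, params@canopySurfaceSd)
      dsm[w$rows, w$cols] <- subD
    }
    ## integer DN outside plots too, plus per-date DSM measurement noise
    R <- round(clamp(R, 0, 255)); G <- round(clamp(G, 0, 255))
    B <- round(clamp(B, 0, 255))
    dsm <- dsm + rnorm(nr * nc, 0, params@dsmNoiseSd)
    SceneStack(day, array(c(R, G, B), dim = c(nr, nc, 3L)), dsm, transform)
  })
}

#' Simulate a full synthetic season
#'
#' Convenience wrapper: layout + truth + rendered scenes for the requested
#' dates. All randomness derives from the single `seed`.
#'
#' @param design a [FieldDesign-class].
#' @param params a [GrowthParams-class] (default [growthParams()]).
#' @param seed master seed.
#' @param dates subset of `design@dates` to render (default all).
#' @return list with `layout` (ground truth attached), `truth`, and
#'   `scenes` (named list of [SceneStack-class], names = days).
#' @examples
#' sim <- simulateSeason(fieldDesign(6, 2, gsd = 0.1, dates = c(6L, 48L)),
#'                       seed = 7)
#' names(sim$scenes)
#' @export
simulateSeason <- function(design, params = growthParams(), seed = 1L,
                           dates = design@dates) {
  stopifnot(all(dates %in% design@dates))
  layout <- generateLayout(design)
  truth <- simulateTruth(layout, params, seed)
  scenes <- lapply(dates, function(d)
    renderScene(layout, truth, d, design, params, seed))
  names(scenes) <- as.character(dates)
  list(layout = attachTruth(layout, truth), truth = truth, scenes = scenes)
}
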