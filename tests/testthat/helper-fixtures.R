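## Shared fixtures: built once per test run, cached across test files.

.fixtures <- new.env(parent = emptyenv())

## A small two-date season (pre-emergence + flowering) used by several
## extraction and recovery tests.
smallSeason <- function() {
  if (is.null(.fixtures$season)) {
    d <- fieldDesign(54, 6, gsd = 0.05, dates = c(6L, 27L, 48L))
    .fixtures$season <- c(simulateSeason(d, seed = 101L),
                          list(design = d, params = growthParams()))
  }
  .fixtures$season
}

## A reduced field at the modeling date with extracted features; sized for
## screening and modeling tests.
modelField <- function() {
  if (is.null(.fixtures$modelField)) {
    d <- fieldDesign(270, 30, gsd = 0.05, dates = c(6L, 48L))
    sim <- simulateSeason(d, seed = 202L)
    dem <- bareDEM(sim$scenes[["6"]], sim$layout)
    ft <- extractPlotFeatures(sim$scenes[["48"]], sim$layout, dem,
                              textureBands = "R")
    .fixtures$modelField <- list(design = d, sim = sim, dem = dem, ft = ft)
  }
  .fixtures$modelField
}

## Random RGB plot block with named bands.
randomBlock <- function(nr = 12L, nc = 10L, seed = 1L) {
  set.seed(seed)
  list(R = matrix(sample(0:255, nr * nc, TRUE), nr, nc),
       G = matrix(sample(0:255, nr * nc, TRUE), nr, nc),
       B = matrix(sample(0:255, nr * nc, TRUE), nr, nc))
}

## Independent brute-force GLCM oracle: enumerate all pixel pairs of each
## offset over a quantized grid, both directions, and normalize.
bruteGLCM <- function(q, levels, offsets) {
  p <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (m in seq_len(nrow(offsets))) {
    dr <- offsets[m, 1]; dc <- offsets[m, 2]
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        a <- q[r, cc] + 1L; b <- q[r2, c2] + 1L
        p[a, b] <- p[a, b] + 1
        p[b, a] <- p[b, a] + 1
      }
    }
  }
  p / sum(p)
}

## Independent double-sum oracle for the nine GLCM metrics.
bruteMetrics <- function(p) {
  L <- nrow(p)
  mu <- 0; for (i in 1:L) for (j in 1:L) mu <- mu + (i - 1) * p[i, j]
  v <- 0; for (i in 1:L) for (j in 1:L) v <- v + (i - 1 - mu)^2 * p[i, j]
  hom <- con <- dis <- ent <- ene <- corn <- autoc <- 0
  for (i in 1:L) for (j in 1:L) {
    d <- (i - 1) - (j - 1)
    hom <- hom + p[i, j] / (1 + d^2)
    con <- con + d^2 * p[i, j]
    dis <- dis + abs(d) * p[i, j]
    if (p[i, j] > 0) ent <- ent - p[i, j] * log(p[i, j])
    ene <- ene + p[i, j]^2
    corn <- corn + (i - 1 - mu) * (j - 1 - mu) * p[i, j]
    autoc <- autoc + (i - 1) * (j - 1) * p[i, j]
  }
  c(mean = mu, variance = v, homogeneity = hom, contrast = con,
    dissimilarity = dis, entropy = ent, energy = ene,
    correlation = if (v < 1e-15) 1 else corn / v, autocorrelation = autoc)
}

## Exhaustive-search Otsu oracle: maximize the between-class variance of
## the quantized sample over every candidate bin split, computing class
## weights and means directly on subsets (no cumulative-histogram
## algebra).
bruteOtsu <- function(x, levels = 256L) {
  lo <- min(x); hi <- max(x)
  q <- pmin(floor((x - lo) / (hi - lo) * levels), levels - 1L)
  best <- -Inf; bestT <- NA
  for (t in 0:(levels - 2L)) {
    lower <- q[q <= t]; upper <- q[q > t]
    if (!length(lower) || !length(upper)) next
    w0 <- length(lower) / length(q)
    s <- w0 * (1 - w0) * (mean(lower) - mean(upper))^2
    if (s > best) { best <- s; bestT <- t }
  }
  list(threshold = lo + (bestT + 1) * (hi - lo) / levels,
       lowerMean = mean(x[q <= bestT]))
}

## Independent scalar oracle for each index, written directly from the
## printed formulas (separate code path from the vectorized registry).
oracleVI <- function(R, G, B, Rmax = 255, Gmax = 255, Bmax = 255) {
  Rn <- R / Rmax; Gn <- G / Gmax; Bn <- B / Bmax
  s <- Rn + Gn + Bn
  r <- Rn / s; g <- Gn / s; b <- Bn / s
  ExG <- 2 * g - r - b
  EXGR <- ExG - 1.4 * r - g
  CIVE <- 18.78745 + 0.44 * r - 0.88 * g + 0.385 * b
  VEG <- g / (r^0.667 * b^(1 - 0.667))
  WI <- (g - b) / abs(r - g)
  c(CIVE = CIVE,
    COMB1 = 0.25 * ExG + 0.3 * EXGR + 0.33 * CIVE + 0.12 * VEG,
    COMB2 = 0.36 * ExG + 0.47 * CIVE + 0.17 * VEG,
    ExG = ExG, EXGR = EXGR,
    GRI = G / R,
    GRVI = (G - R) / (G + R),
    MGRVI = (G^2 - R^2) / (G^2 + R^2),
    PPRb = (G - B) / (G + B),
    RGBVI = (G^2 - R * B) / (G^2 + R * B),
    SAVI = 1.5 * (G - R) / (G + R + 0.5),
    VARI = (G - R) / (G + R - B),
    VDVI = (2 * G - R - B) / (2 * G + R + B),
    VEG = VEG, WI = WI)
}

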