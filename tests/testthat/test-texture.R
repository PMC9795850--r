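## GLCM texture: quantization, co-occurrence counting, metrics,
## plot-level aggregation.

test_that("quantization bins DN ranges linearly", {
  expect_identical(as.integer(quantizeGrid(matrix(c(0, 255), 1), 2L)),
                   c(0L, 1L))
  expect_identical(as.integer(quantizeGrid(matrix(c(0, 85, 170, 255), 1),
                                           4L)), 0:3)
  expect_true(all(quantizeGrid(matrix(7, 5, 5), 32L) == 0L))
  expect_error(quantizeGrid(matrix(1), 1L), "levels")
})

test_that("glcm matches brute-force pair enumeration on random grids", {
  cfg <- glcmConfig(levels = 4L)
  for (seed in 1:5) {
    set.seed(seed)
    q <- matrix(sample(0:3, 25, TRUE), 5, 5)
    expect_equal(glcm(q, cfg), bruteGLCM(q, 4L, cfg$offsets),
                 tolerance = 1e-14)
  }
  set.seed(99)
  q16 <- matrix(sample(0:7, 256, TRUE), 16, 16)
  cfg8 <- glcmConfig(levels = 8L)
  expect_equal(glcm(q16, cfg8), bruteGLCM(q16, 8L, cfg8$offsets),
               tolerance = 1e-14)
})

test_that("glcm degenerate and structured windows behave as constructed", {
  cfg <- glcmConfig(levels = 2L)
  p <- glcm(matrix(0L, 3, 3), cfg)
  expect_equal(p[1, 1], 1)
  expect_equal(sum(p), 1)
  ## vertical stripes, horizontal offset only: all mass on (0,1)/(1,0)
  stripes <- matrix(rep(c(0L, 1L), each = 4, times = 2), 4, 4)
  ph <- glcm(stripes, glcmConfig(levels = 2L,
                                 offsets = matrix(c(0L, 1L), 1)))
  expect_equal(ph[1, 1] + ph[2, 2], 0)
  expect_equal(ph[1, 2], 0.5)
  expect_error(glcm(matrix(0L, 1, 1), cfg), "offset reach")
})

test_that("the nine metrics match the double-sum oracle", {
  ## degenerate matrix
  p0 <- matrix(0, 4, 4); p0[1, 1] <- 1
  m0 <- glcmMetrics(p0)
  expect_equal(unname(m0[c("energy", "entropy", "contrast",
                           "homogeneity", "correlation")]),
               c(1, 0, 0, 1, 1))
  ## uniform over 4 cells
  pu <- matrix(0, 4, 4); pu[1:2, 1:2] <- 0.25
  mu <- glcmMetrics(pu)
  expect_equal(unname(mu["entropy"]), log(4), tolerance = 1e-12)
  expect_equal(unname(mu["energy"]), 0.25, tolerance = 1e-12)
  ## random normalized matrices at 8 levels
  for (seed in 1:5) {
    set.seed(seed)
    p <- matrix(runif(64), 8, 8); p <- (p + t(p)); p <- p / sum(p)
    expect_equal(glcmMetrics(p), bruteMetrics(p), tolerance = 1e-12)
  }
  expect_error(glcmMetrics(matrix(1, 2, 2)), "not normalized")
})

test_that("compiled sliding-window metrics agree with the R path", {
  set.seed(21)
  g <- matrix(sample(0:255, 8 * 9, TRUE), 8, 9)
  cfg <- glcmConfig(levels = 8L)
  q <- quantizeGrid(g, 8L)
  met <- uavyield:::.glcmWindowMetrics(q, 8L, 3L, 3L, cfg$offsets)
  ## compare every window against glcm() + glcmMetrics()
  w <- 0L
  for (c0 in 1:(ncol(q) - 2)) for (r0 in 1:(nrow(q) - 2)) {
    w <- w + 1L
    win <- q[r0:(r0 + 2), c0:(c0 + 2)]
    expect_equal(unname(met[w, ]), unname(glcmMetrics(glcm(win, cfg))),
                 tolerance = 1e-12)
  }
})

test_that("plot texture block sizes are exact: 45 per band, 135 for RGB", {
  blk <- randomBlock(10, 8, seed = 5)
  t3 <- plotTextureFeatures(blk)
  expect_length(t3, 135L)
  t1 <- plotTextureFeatures(blk, bands = "R")
  expect_length(t1, 45L)
  expect_true(all(grepl("^R_", names(t1))))
  ## feature count invariant to plot size
  expect_length(plotTextureFeatures(randomBlock(25, 4, seed = 6),
                                    bands = "G"), 45L)
  expect_error(plotTextureFeatures(randomBlock(2, 2, seed = 7)),
               "smaller than")
})

test_that("constant plots collapse the statistics; noise raises entropy", {
  blk <- list(R = matrix(50, 8, 8), G = matrix(50, 8, 8),
              B = matrix(50, 8, 8))
  tv <- plotTextureFeatures(blk, bands = "R")
  expect_equal(unname(tv["R_energy_mean"]), 1)
  expect_equal(unname(tv["R_entropy_mean"]), 0)
  expect_equal(unname(tv["R_contrast_max"]), 0)
  for (mn in glcmMetricNames()) {
    expect_equal(unname(tv[paste0("R_", mn, "_min")]),
                 unname(tv[paste0("R_", mn, "_max")]), label = mn)
    expect_equal(unname(tv[paste0("R_", mn, "_sd")]), 0, label = mn)
  }
  ## salt-and-pepper noise strictly increases mean entropy (over seeds)
  ents <- vapply(1:5, function(s) {
    set.seed(s)
    noisy <- blk$R
    ix <- sample(length(noisy), 16)
    noisy[ix] <- sample(c(0, 255), 16, TRUE)
    unname(plotTextureFeatures(list(R = noisy, G = noisy, B = noisy),
                               bands = "R")["R_entropy_mean"])
  }, numeric(1))
  expect_true(all(ents > 0))
})
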