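## Layout generation, ground-truth simulation, scene rendering.

test_that("default design lays out 1805 plots of 1.8 x 0.8 m", {
  d <- fieldDesign()
  layout <- generateLayout(d)
  expect_identical(nrow(layout), 1805L)
  expect_identical(sum(layout$is_control), 190L)
  expect_true(all(abs((layout$xmax - layout$xmin) - 0.8) < 1e-12))
  expect_true(all(abs((layout$ymax - layout$ymin) - 1.8) < 1e-12))
  ## non-overlapping rectangles separated by furrow gaps: pairwise
  ## distinct corner combinations on the grid
  key <- paste(layout$xmin, layout$ymin)
  expect_identical(anyDuplicated(key), 0L)
})

test_that("a single-plot design sits at the origin with area 1.44 m2", {
  layout <- generateLayout(fieldDesign(1, 0))
  expect_identical(nrow(layout), 1L)
  expect_equal(layout$xmin, 0)
  expect_equal(layout$ymin, 0)
  expect_equal((layout$xmax - layout$xmin) * (layout$ymax - layout$ymin),
               1.44)
})

test_that("layout is deterministic and seed-independent", {
  d <- fieldDesign(10, 2)
  expect_identical(generateLayout(d), generateLayout(d))
  expect_error(fieldDesign(0, 0), "positive")
  expect_error(fieldDesign(10, 2, gsd = 0), "gsd")
  expect_error(fieldDesign(10, 2, dates = c(10L, 10L)))
})

test_that("the yield model is the stated linear form in lodging", {
  layout <- generateLayout(fieldDesign(40, 0))
  p <- growthParams(grainNumberCoef = c(60, 0, 0, -5),
                    grainNumberSd = 1e-9, heightMaxSd = 1e-9,
                    grainWeightSd = 1e-9)
  tr <- simulateTruth(layout, p, seed = 5)
  expect_true(all(tr$lodging %in% 1:5))
  expect_equal(tr$grain_number, 60 - 5 * (tr$lodging - 1),
               tolerance = 1e-6)
})

test_that("population moments match the calibrated trial at n = 1805", {
  layout <- generateLayout(fieldDesign())
  tr <- simulateTruth(layout, growthParams(), seed = 7)
  ## means calibrated from the printed RMSE / rRMSE ratios
  expect_lt(abs(mean(tr$grain_number) - 59.3) / 59.3, 0.15)
  expect_lt(abs(mean(tr$grain_weight) - 9.26) / 9.26, 0.15)
  expect_true(all(tr$grain_number >= 0))
  expect_true(all(tr$grain_weight >= 0))
  expect_true(all(tr$lodging %in% 1:5))
  ## lodging marginal skewed toward level 1
  expect_gt(mean(tr$lodging == 1), 0.4)
  ## reproducibility from the seed
  tr2 <- simulateTruth(layout, growthParams(), seed = 7)
  expect_identical(tr, tr2)
})

test_that("canopy growth is non-decreasing up to its plateau", {
  sea <- smallSeason()
  days <- seq(6, 54, by = 3)
  fr <- vapply(days, function(dd)
    canopyFractionAt(sea$truth, dd, sea$params), numeric(nrow(sea$truth)))
  expect_true(all(diff(t(fr)) >= -1e-12))
  expect_true(all(fr >= 0 & fr <= 1))
  h <- vapply(days, function(dd)
    plantHeightAt(sea$truth, dd, sea$params), numeric(nrow(sea$truth)))
  expect_true(all(h >= 0))
})

test_that("rendered canopy pixel counts match the truth fraction", {
  sea <- smallSeason()
  sc <- sea$scenes[["27"]]
  fr <- canopyFractionAt(sea$truth, 27, sea$params)
  for (i in c(3L, 30L)) {
    blk <- clipPlot(sc, sea$layout[i, ])
    npix <- prod(dim(blk$dsm))
    egi <- (2 * blk$rgb[, , 2] - blk$rgb[, , 1] - blk$rgb[, , 3]) /
      pmax(blk$rgb[, , 2], 1)
    expect_lte(abs(sum(egi > 0.05) - round(fr[i] * npix)), 1)
  }
})

test_that("canopy DSM equals base + height when noise is switched off", {
  d <- fieldDesign(4, 0, gsd = 0.1, dates = c(6L, 48L))
  p <- growthParams(terrainSd = 0, dsmNoiseSd = 0, canopySurfaceSd = 0,
                    heightMaxSd = 1e-9)
  layout <- generateLayout(d)
  tr <- simulateTruth(layout, p, seed = 3)
  sc <- renderScene(layout, tr, 48L, d, p, seed = 3)
  hgt <- plantHeightAt(tr, 48, p)
  blk <- clipPlot(sc, layout[1, ])
  canopy <- canopyCover(blk)$mask
  expect_equal(unname(blk$dsm[canopy]),
               rep(22 + hgt[1], sum(canopy)), tolerance = 1e-9)
  expect_equal(unname(blk$dsm[!canopy]), rep(22, sum(!canopy)),
               tolerance = 1e-9)
})

test_that("rendering is reproducible and rejects off-schedule dates", {
  d <- fieldDesign(6, 0, gsd = 0.1, dates = c(6L, 48L))
  layout <- generateLayout(d)
  tr <- simulateTruth(layout, growthParams(), seed = 9)
  s1 <- renderScene(layout, tr, 48L, d, growthParams(), seed = 9)
  s2 <- renderScene(layout, tr, 48L, d, growthParams(), seed = 9)
  expect_identical(sceneRGB(s1), sceneRGB(s2))
  expect_identical(sceneDSM(s1), sceneDSM(s2))
  expect_error(renderScene(layout, tr, 47L, d, growthParams(), seed = 9),
               "schedule")
})

test_that("the first scheduled date is pre-emergence", {
  sea <- smallSeason()
  fr <- canopyFractionAt(sea$truth, 6, sea$params)
  expect_true(all(fr < 0.02))
  sc6 <- sea$scenes[["6"]]
  blk <- clipPlot(sc6, sea$layout[1, ])
  expect_lt(canopyCover(blk)$fraction, 0.05)
})
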