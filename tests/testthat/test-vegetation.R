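## Vegetation indices and canopy cover.

test_that("hand-checked pixel values at (100, 200, 50) with equal maxima", {
  bands <- normalizeBands(list(R = matrix(100), G = matrix(200),
                               B = matrix(50)),
                          maxima = c(255, 255, 255))
  expect_equal(bands$r[1], 0.2857, tolerance = 1e-3)
  expect_equal(bands$g[1], 0.5714, tolerance = 1e-3)
  expect_equal(bands$b[1], 0.1429, tolerance = 1e-3)
  expect_equal(computeIndex("ExG", bands)[1], 0.7143, tolerance = 1e-3)
  expect_equal(computeIndex("WI", bands)[1], 1.5, tolerance = 1e-10)
  expect_equal(computeIndex("CIVE", bands)[1], 18.4653, tolerance = 1e-5)
  expect_equal(computeIndex("GRVI", bands)[1], 1 / 3, tolerance = 1e-10)
  expect_equal(computeIndex("GRI", bands)[1], 2, tolerance = 1e-10)
  expect_equal(computeIndex("MGRVI", bands)[1], 0.6, tolerance = 1e-10)
})

test_that("all 15 formulas match the independent oracle on 1000 random pixels", {
  set.seed(11)
  n <- 1000L
  R <- sample(1:255, n, TRUE); G <- sample(1:255, n, TRUE)
  B <- sample(1:255, n, TRUE)
  bands <- normalizeBands(list(R = matrix(R, 1), G = matrix(G, 1),
                               B = matrix(B, 1)),
                          maxima = c(max(R), max(G), max(B)))
  expected <- t(vapply(seq_len(n), function(i)
    oracleVI(R[i], G[i], B[i], max(R), max(G), max(B)), numeric(15)))
  for (nm in colnames(expected)) {
    got <- as.numeric(computeIndex(nm, bands))
    want <- expected[, nm]
    ok <- is.finite(want)
    expect_true(all(abs(got[ok] - want[ok]) < 1e-10), label = nm)
  }
})

test_that("gray pixels are symmetric: r = g = b = 1/3 and zero indices", {
  bands <- normalizeBands(list(R = matrix(120), G = matrix(120),
                               B = matrix(120)),
                          maxima = c(255, 255, 255))
  expect_equal(bands$r[1], 1 / 3, tolerance = 1e-12)
  expect_equal(bands$g[1], 1 / 3, tolerance = 1e-12)
  for (nm in c("ExG", "GRVI", "MGRVI", "VDVI"))
    expect_equal(as.numeric(computeIndex(nm, bands)), 0, tolerance = 1e-12)
  expect_true(is.na(computeIndex("WI", bands)[1])) # |r - g| = 0
})

test_that("chromatic closure holds and zero pixels are excluded", {
  blk <- randomBlock(8, 8, seed = 3)
  blk$R[1, 1] <- blk$G[1, 1] <- blk$B[1, 1] <- 0L
  bands <- normalizeBands(blk)
  s <- bands$r + bands$g + bands$b
  expect_true(all(abs(s[bands$valid] - 1) < 1e-12))
  expect_false(bands$valid[1, 1])
  expect_error(normalizeBands(list(R = matrix(0), G = matrix(0),
                                   B = matrix(0))), "all-black")
})

test_that("ratio indices are invariant to global DN scaling", {
  blk <- randomBlock(6, 6, seed = 4)
  blk2 <- lapply(blk, function(m) m * 0.5)
  b1 <- normalizeBands(blk); b2 <- normalizeBands(blk2)
  for (nm in c("VEG", "WI", "GRI", "GRVI", "MGRVI", "PPRb", "VARI", "VDVI"))
    expect_equal(computeIndex(nm, b1), computeIndex(nm, b2),
                 tolerance = 1e-9, label = nm)
  expect_equal(b1$r, b2$r, tolerance = 1e-12)
  ## SAVI has an additive soil term: re-evaluate directly instead
  expect_equal(as.numeric(computeIndex("SAVI", b2)),
               as.numeric(1.5 * (blk2$G - blk2$R) /
                            (blk2$G + blk2$R + 0.5)), tolerance = 1e-12)
})

test_that("plot VI block has 24 stable features and linear means", {
  blk <- list(R = matrix(100, 4, 4), G = matrix(200, 4, 4),
              B = matrix(50, 4, 4))
  v <- plotVIFeatures(blk, maxima = c(255, 255, 255))
  expect_length(v, 24L)
  expect_identical(names(v), viFeatureNames())
  ## constant plot: means equal single-pixel values
  bands <- normalizeBands(list(R = matrix(100), G = matrix(200),
                               B = matrix(50)), maxima = c(255, 255, 255))
  expect_equal(unname(v["ExG"]), as.numeric(computeIndex("ExG", bands)),
               tolerance = 1e-12)
  ## half/half plot: mean is the average (gray pixels have ExG = 0
  ## under equal maxima)
  blk2 <- list(R = cbind(matrix(100, 4, 2), matrix(120, 4, 2)),
               G = cbind(matrix(200, 4, 2), matrix(120, 4, 2)),
               B = cbind(matrix(50, 4, 2), matrix(120, 4, 2)))
  bands1 <- normalizeBands(list(R = matrix(100), G = matrix(200),
                                B = matrix(50)), maxima = c(255, 255, 255))
  exg1 <- as.numeric(computeIndex("ExG", bands1))
  v2 <- plotVIFeatures(blk2, maxima = c(255, 255, 255))
  expect_equal(unname(v2["ExG"]), (exg1 + 0) / 2, tolerance = 1e-12)
  expect_error(computeIndex("NDVI", bands1), "valid names")
})

test_that("EGI canopy segmentation matches hand arithmetic", {
  ## (100,200,50): EGI = (400-100-50)/200 = 1.25 -> canopy
  cc <- canopyCover(list(R = matrix(100), G = matrix(200), B = matrix(50)))
  expect_true(cc$mask[1])
  ## gray pixel: EGI = 0 <= 0.05 -> soil
  cc2 <- canopyCover(list(R = matrix(80), G = matrix(80), B = matrix(80)))
  expect_false(cc2$mask[1])
  expect_equal(cc2$fraction, 0)
  expect_error(canopyCover(list(R = matrix(nrow = 0, ncol = 0),
                                G = matrix(nrow = 0, ncol = 0),
                                B = matrix(nrow = 0, ncol = 0))), "empty")
})

test_that("raising the EGI threshold never increases coverage", {
  blk <- randomBlock(15, 15, seed = 9)
  fr <- vapply(seq(-0.5, 1.5, by = 0.1),
               function(th) canopyCover(blk, th)$fraction, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("rendered scenes honour the EGI contract and round-trip cover", {
  sea <- smallSeason()
  sc <- sea$scenes[["48"]]
  fr <- canopyFractionAt(sea$truth, 48, sea$params)
  for (i in c(1L, 20L, 41L)) {
    blk <- clipPlot(sc, sea$layout[i, ])
    cc <- canopyCover(blk)
    expect_lt(abs(cc$fraction - fr[i]), 0.02)
  }
})
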