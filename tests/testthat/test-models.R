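## Train/validation split, evaluation metrics, the five regressors.

test_that("the 70/30 split is exact, disjoint and reproducible", {
  s <- splitData(1805, seed = 4)
  expect_length(s$train, 1263L)
  expect_length(s$validation, 542L)
  expect_length(intersect(s$train, s$validation), 0L)
  expect_setequal(c(s$train, s$validation), 1:1805)
  expect_identical(splitData(1805, seed = 4), s)
  expect_false(identical(splitData(1805, seed = 5)$train, s$train))
  expect_error(splitData(1805, trainFraction = 1), "between 0 and 1")
  expect_error(splitData(5), "at least 10")
})

test_that("metrics satisfy their exact identities and hand values", {
  obs <- c(10, 20, 30); pred <- c(12, 18, 33)
  m <- regressionMetrics(obs, pred)
  expect_equal(unname(m["rmse"]), 2.3805, tolerance = 1e-4)
  expect_equal(unname(m["rrmse"]), 11.90, tolerance = 1e-2)
  ## perfect prediction
  mp <- regressionMetrics(obs, obs)
  expect_equal(unname(mp), c(1, 0, 0))
  ## mean predictor has R2 = 0
  mm <- regressionMetrics(obs, rep(mean(obs), 3))
  expect_equal(unname(mm["r2"]), 0)
  ## rRMSE / RMSE = 100 / mean(obs) exactly
  set.seed(8)
  o <- runif(50, 5, 50); p <- o + rnorm(50)
  mo <- regressionMetrics(o, p)
  expect_equal(unname(mo["rrmse"] / mo["rmse"]), 100 / mean(o),
               tolerance = 1e-12)
  expect_warning(regressionMetrics(c(-1, 1), c(0, 0)), "rRMSE")
  expect_error(regressionMetrics(1:3, 1:2), "length")
})

test_that("all five methods fit a noiseless linear target almost exactly", {
  set.seed(12)
  n <- 120L; p <- 6L
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  beta <- c(3, -2, 1, 0.5, -1, 2)
  y <- drop(X %*% beta) + 50
  tr <- 1:90; va <- 91:120
  for (m in yieldMethods()) {
    res <- fitPredict(m, X[tr, ], y[tr], X[va, ], y[va], seed = 1)
    ## bootstrap smoothing (forests) and the unit-margin budget (SVR)
    ## keep those two just short of interpolation
    lo <- c(PLSR = 0.99, Logistic = 0.99, RFR = 0.9, SVM = 0.95,
            DNN = 0.99)
    expect_gt(modelMetrics(res, "train")[["r2"]], lo[[m]], label = m)
  }
})

test_that("a permuted response yields near-zero validation R2", {
  r2s <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 100L
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- sample(drop(X %*% c(2, -1, 1, 0, 1)) + 30)
    res <- fitPredict("Logistic", X[1:70, ], y[1:70], X[71:100, ],
                      y[71:100], seed = s)
    modelMetrics(res, "validation")[["r2"]]
  }, numeric(1))
  expect_lt(mean(r2s), 0.1)
})

test_that("fits are deterministic given the seed", {
  set.seed(33)
  n <- 80L
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- drop(X %*% c(1, 2, -1, 0.5)) + rnorm(n) + 20
  for (m in yieldMethods()) {
    r1 <- fitPredict(m, X[1:60, ], y[1:60], X[61:80, ], y[61:80], seed = 7)
    r2 <- fitPredict(m, X[1:60, ], y[1:60], X[61:80, ], y[61:80], seed = 7)
    expect_identical(modelPredictions(r1)$predicted,
                     modelPredictions(r2)$predicted, label = m)
  }
  expect_error(fitPredict("PLSR", X[1:60, ], rep(1, 60), X[61:80, ],
                          y[61:80]), "degenerate")
})

test_that("the SIMPLS fit agrees with an established PLS implementation", {
  set.seed(44)
  n <- 60L; p <- 8L
  X <- scale(matrix(rnorm(n * p), n, p))
  y <- drop(X %*% rnorm(p)) + rnorm(n, 0, 0.5)
  colnames(X) <- paste0("v", 1:p)
  fit <- uavyield:::simplsFit(X, y, 3L)
  pred <- uavyield:::simplsPredict(fit, X, 3L)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression",
                       scale = FALSE)
  refPred <- predict(ref, X)$predict[, 1, 3]
  expect_gt(cor(pred, refPred), 0.99999)
  expect_equal(mean((y - pred)^2), mean((y - refPred)^2),
               tolerance = 1e-6)
})

test_that("model results carry disjoint splits and valid metrics", {
  set.seed(55)
  n <- 60L
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, 1, 1)) + 10 + rnorm(n, 0, 0.2)
  res <- fitPredict("SVM", X[1:40, ], y[1:40], X[41:60, ], y[41:60],
                    trainIds = paste0("P", 1:40),
                    valIds = paste0("P", 41:60),
                    featureSet = "VIs", target = "grain_number")
  expect_s4_class(res, "ModelResult")
  tab <- resultsTable(list(res))
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$rmse >= 0))
  expect_true(all(tab$r2 <= 1))
})
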