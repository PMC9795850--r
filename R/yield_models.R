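## Five regression families with fixed hyperparameters, the 70/30 split,
## and the evaluation metrics (R2, RMSE, rRMSE).

#' Names of the five regression methods
#' @return character vector: PLSR, Logistic (penalized linear), RFR,
#'   SVM, DNN.
#' @export
yieldMethods <- function() c("PLSR", "Logistic", "RFR", "SVM", "DNN")

#' Split plots into training and validation sets
#'
#' Disjoint, exhaustive, by-plot random split reproducible from `seed`;
#' the training set holds `floor(trainFraction * n)` plots.
#'
#' @param x plot table (data.frame) or total number of plots.
#' @param trainFraction fraction of plots in the training set, in (0, 1)
#'   exclusive (default 0.7).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `validation`.
#' @examples
#' s <- splitData(1805, seed = 1)
#' lengths(s) # 1263 / 542
#' @export
splitData <- function(x, trainFraction = 0.7, seed = 1L) {
  n <- if (is.data.frame(x)) nrow(x) else as.integer(x)
  if (n < 10L) stop("need at least 10 plots to split")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  k <- floor(trainFraction * n)
  tr <- withSeed(derivedSeed(seed, 31L), sort(sample.int(n, k)))
  list(train = tr, validation = setdiff(seq_len(n), tr))
}

#' Regression evaluation metrics
#'
#' `R2 = 1 - SSres/SStot`, `RMSE = sqrt(mean((obs - pred)^2))`, and
#' `rRMSE = 100 * RMSE / mean(obs)` (per cent). The rRMSE is undefined
#' (returned as `NA` with a warning) when the observed mean is zero.
#'
#' @param observed,predicted paired numeric vectors, length >= 2.
#' @return named numeric `(r2, rmse, rrmse)`.
#' @export
regressionMetrics <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length")
  if (length(observed) < 2L) stop("need at least 2 pairs")
  ssres <- sum((observed - predicted)^2)
  sstot <- sum((observed - mean(observed))^2)
  r2 <- if (sstot == 0) as.numeric(ssres == 0) else 1 - ssres / sstot
  rmse <- sqrt(mean((observed - predicted)^2))
  m <- mean(observed)
  rrmse <- if (m == 0) {
    warning("observed mean is zero: rRMSE undefined")
    NA_real_
  } else 100 * rmse / m
  c(r2 = r2, rmse = rmse, rrmse = rrmse)
}

## ---------------------------------------------------------------------------
## PLSR (SIMPLS) with leave-one-out component selection
## ---------------------------------------------------------------------------

## SIMPLS on centred data; returns coefficient matrix for 1..ncomp
## components plus the centres, so predictions for all component counts
## come from one fit.
simplsFit <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, p, n - 1L)
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar)
  yc <- y - ybar
  S <- crossprod(Xc, yc)
  R <- matrix(0, p, ncomp); V <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  B <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    r <- S
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) { ncomp <- a - 1L; break }
    t <- t / nt; r <- r / nt
    pl <- crossprod(Xc, t)
    q <- sum(yc * t)
    v <- pl
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pl)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; V[, a] <- v; Q[a] <- q
    B[, a] <- R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
  }
  list(B = B[, seq_len(max(ncomp, 1L)), drop = FALSE],
       xbar = xbar, ybar = ybar, ncomp = max(ncomp, 1L))
}

simplsPredict <- function(fit, X, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  drop(sweep(X, 2L, fit$xbar) %*% fit$B[, ncomp]) + fit$ybar
}

## Leave-one-out PRESS over 1..maxComp components.
simplsLOO <- function(X, y, maxComp = 5L) {
  n <- nrow(X)
  maxComp <- min(maxComp, ncol(X), n - 2L)
  press <- numeric(maxComp)
  for (i in seq_len(n)) {
    f <- simplsFit(X[-i, , drop = FALSE], y[-i], maxComp)
    for (a in seq_len(maxComp))
      press[a] <- press[a] +
        (y[i] - simplsPredict(f, X[i, , drop = FALSE],
                              min(a, f$ncomp)))^2
  }
  which.min(press)
}

## ---------------------------------------------------------------------------
## Minimal feed-forward network (2 x 200 ReLU, SGD)
## ---------------------------------------------------------------------------

mlpFit <- function(X, y, hidden = c(200L, 200L), epochs = 10L,
                   lr = 0.005, batch = 1L, clip = 50, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  withSeed(seed, {
    W1 <- matrix(rnorm(p * hidden[1], 0, sqrt(2 / p)), p, hidden[1])
    W2 <- matrix(rnorm(hidden[1] * hidden[2], 0, sqrt(2 / hidden[1])),
                 hidden[1], hidden[2])
    W3 <- matrix(rnorm(hidden[2], 0, sqrt(2 / hidden[2])), hidden[2], 1)
    b1 <- rep(0, hidden[1]); b2 <- rep(0, hidden[2]); b3 <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (s in seq(1L, n, by = batch)) {
        ix <- ord[s:min(s + batch - 1L, n)]
        Xb <- X[ix, , drop = FALSE]
        yb <- y[ix]
        m <- length(ix)
        A1 <- sweep(Xb %*% W1, 2L, b1, "+"); H1 <- pmax(A1, 0)
        A2 <- sweep(H1 %*% W2, 2L, b2, "+"); H2 <- pmax(A2, 0)
        yh <- drop(H2 %*% W3) + b3
        d3 <- matrix((yh - yb) / m, m, 1)
        dW3 <- crossprod(H2, d3); db3 <- sum(d3)
        d2 <- (d3 %*% t(W3)) * (A2 > 0)
        dW2 <- crossprod(H1, d2); db2 <- colSums(d2)
        d1 <- (d2 %*% t(W2)) * (A1 > 0)
        dW1 <- crossprod(Xb, d1); db1 <- colSums(d1)
        ## global gradient-norm clipping keeps per-sample SGD stable on
        ## wide feature sets
        gn <- sqrt(sum(dW1^2) + sum(dW2^2) + sum(dW3^2) +
                     sum(db1^2) + sum(db2^2) + db3^2)
        if (is.finite(gn) && gn > clip) {
          sc <- clip / gn
          dW1 <- dW1 * sc; dW2 <- dW2 * sc; dW3 <- dW3 * sc
          db1 <- db1 * sc; db2 <- db2 * sc; db3 <- db3 * sc
        }
        W3 <- W3 - lr * dW3; b3 <- b3 - lr * db3
        W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
        W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
      }
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
  })
}

mlpPredict <- function(fit, X) {
  H1 <- pmax(sweep(X %*% fit$W1, 2L, fit$b1, "+"), 0)
  H2 <- pmax(sweep(H1 %*% fit$W2, 2L, fit$b2, "+"), 0)
  drop(H2 %*% fit$W3) + fit$b3
}

## ---------------------------------------------------------------------------
## fitPredict
## ---------------------------------------------------------------------------

#' Fit one regression method and evaluate on both splits
#'
#' Features are standardized with the training-set mean and SD (no
#' leakage); targets are left untransformed (the network standardizes its
#' response internally for optimization and back-transforms the
#' predictions). Method hyperparameters are fixed:
#'
#' * `PLSR` — SIMPLS with up to 5 components, the count chosen by
#'   leave-one-out cross-validated PRESS.
#' * `Logistic` — penalized linear regression over a 10-fold
#'   cross-validated lambda path ([glmnet::cv.glmnet()]), prediction at
#'   `lambda.min`. (The trial's targets are continuous, so the
#'   lambda-path 10-fold procedure is applied to a Gaussian likelihood.)
#' * `RFR` — random forest, 500 trees, `mtry = floor(p/3)`.
#' * `SVM` — radial-basis support-vector regression, `gamma = 1/p`,
#'   `epsilon = 0.01`, tolerance 0.001.
#' * `DNN` — feed-forward network, two hidden layers of 200 rectified
#'   units, per-sample SGD with global gradient-norm clipping,
#'   10 epochs, learning rate 0.005.
#'
#' All methods are deterministic given `seed`.
#'
#' @param method one of [yieldMethods()].
#' @param trainX,trainY training features (matrix) and response.
#' @param valX,valY validation features and response.
#' @param seed integer seed.
#' @param featureSet,target labels carried into the result.
#' @param trainIds,valIds optional plot identifiers.
#' @return a [ModelResult-class].
#' @export
fitPredict <- function(method, trainX, trainY, valX, valY, seed = 1L,
                       featureSet = "", target = "",
                       trainIds = NULL, valIds = NULL) {
  method <- match.arg(method, yieldMethods())
  trainX <- as.matrix(trainX); valX <- as.matrix(valX)
  p <- ncol(trainX)
  if (p == 0L) stop("no predictors")
  if (var(trainY) == 0) stop("degenerate training target variance")
  mu <- colMeans(trainX)
  s <- apply(trainX, 2L, sd); s[s < 1e-8] <- 1
  ## clamp standardized features: heavy-tailed texture CV statistics
  ## can land hundreds of train-SDs out and destabilize linear fits
  Ztr <- clamp(sweep(sweep(trainX, 2L, mu), 2L, s, "/"), -8, 8)
  Zva <- clamp(sweep(sweep(valX, 2L, mu), 2L, s, "/"), -8, 8)
  pred <- switch(method,
    PLSR = {
      nc <- simplsLOO(Ztr, trainY, 5L)
      fit <- simplsFit(Ztr, trainY, nc)
      list(tr = simplsPredict(fit, Ztr), va = simplsPredict(fit, Zva))
    },
    Logistic = {
      fit <- withSeed(derivedSeed(seed, 7L),
                      glmnet::cv.glmnet(Ztr, trainY, nfolds = 10L,
                                        family = "gaussian"))
      list(tr = drop(predict(fit, Ztr, s = "lambda.min")),
           va = drop(predict(fit, Zva, s = "lambda.min")))
    },
    RFR = {
      fit <- ranger::ranger(x = as.data.frame(Ztr), y = trainY,
                            num.trees = 500L,
                            mtry = max(1L, floor(p / 3)),
                            seed = derivedSeed(seed, 8L),
                            num.threads = 1L, verbose = FALSE)
      list(tr = predict(fit, as.data.frame(Ztr),
                        num.threads = 1L)$predictions,
           va = predict(fit, as.data.frame(Zva),
                        num.threads = 1L)$predictions)
    },
    SVM = {
      ## response standardized for the margin scale (the reference
      ## implementation's default), back-transformed after prediction
      ybar <- mean(trainY); ysd <- sd(trainY)
      fit <- e1071::svm(Ztr, (trainY - ybar) / ysd,
                        type = "eps-regression",
                        kernel = "radial", gamma = 1 / p,
                        epsilon = 0.01, tolerance = 0.001, scale = FALSE)
      list(tr = as.numeric(predict(fit, Ztr)) * ysd + ybar,
           va = as.numeric(predict(fit, Zva)) * ysd + ybar)
    },
    DNN = {
      ybar <- mean(trainY); ysd <- sd(trainY)
      fit <- mlpFit(Ztr, (trainY - ybar) / ysd,
                    seed = derivedSeed(seed, 9L))
      list(tr = mlpPredict(fit, Ztr) * ysd + ybar,
           va = mlpPredict(fit, Zva) * ysd + ybar)
    })
  if (is.null(trainIds)) trainIds <- paste0("train", seq_along(trainY))
  if (is.null(valIds)) valIds <- paste0("val", seq_along(valY))
  new("ModelResult",
      method = method, featureSet = featureSet, target = target,
      train = regressionMetrics(trainY, pred$tr),
      validation = regressionMetrics(valY, pred$va),
      predictions = data.frame(
        plotId = c(trainIds, valIds),
        split = rep(c("train", "validation"),
                    c(length(trainY), length(valY))),
        observed = c(trainY, valY),
        predicted = c(pred$tr, pred$va),
        stringsAsFactors = FALSE))
}
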