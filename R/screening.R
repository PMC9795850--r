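## Feature screening: shadow-feature (Boruta-style) selection with the
## 80-of-100 removal rule, and one-class SVM outlier rejection.

#' Augment a feature matrix with shadow copies
#'
#' For every real column, appends a shadow column holding the same values
#' in a random row order, doubling the column count. Shadow columns keep
#' the marginal distribution of their source exactly (same multiset of
#' values) while destroying any association with the response; they are
#' named `shadow_<source>`.
#'
#' @param X numeric matrix with >= 2 rows and named columns.
#' @param seed integer seed.
#' @return matrix with `2 * ncol(X)` columns.
#' @export
shadowAugment <- function(X, seed = 1L) {
  if (is.null(dim(X)) || nrow(X) < 2L || ncol(X) < 1L)
    stop("X must be a matrix with at least 2 rows and 1 column")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sh <- withSeed(seed, apply(X, 2L, sample))
  colnames(sh) <- paste0("shadow_", colnames(X))
  cbind(X, sh)
}

#' Random-forest permutation importance
#'
#' Fits a random forest on the (typically shadow-augmented) matrix and
#' returns out-of-bag permutation importance per column — the regression
#' analogue of "average reduction in precision": the increase in
#' out-of-bag error when a column is permuted.
#'
#' @param Xaug numeric feature matrix (real + shadow columns).
#' @param y numeric response.
#' @param numTrees trees per forest (default 500, the size used for the
#'   regression forests).
#' @param mtry variables tried per split (default `floor(sqrt(p))`, the
#'   usual importance-forest convention; importance estimates with large
#'   mtry concentrate on the strongest member of each correlated feature
#'   family).
#' @param seed integer seed.
#' @return named numeric importance vector, one value per column.
#' @export
rfImportance <- function(Xaug, y, numTrees = 500L, mtry = NULL, seed = 1L) {
  if (nrow(Xaug) != length(y)) stop("rows of X must match length of y")
  if (var(y) == 0) stop("constant response: importance undefined")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(Xaug))))
  fit <- ranger::ranger(
    x = as.data.frame(Xaug), y = y,
    num.trees = numTrees, mtry = mtry,
    importance = "permutation",
    seed = seed, num.threads = 1L, verbose = FALSE)
  fit$variable.importance
}

#' Shadow-feature screening over repeated rankings
#'
#' Runs `nRuns` independent rounds of shadow augmentation plus
#' random-forest permutation importance, counts for each real feature the
#' runs in which its importance fell below the best (maximum) shadow
#' importance, and removes a feature iff that count reaches `cutoff`
#' (default 80 of 100). Features named in `exclude` (by convention the
#' lodging score and canopy cover) never enter the screening and are
#' always kept.
#'
#' @param X numeric feature matrix (named columns).
#' @param y numeric response.
#' @param nRuns number of ranking runs (default 100).
#' @param cutoff removal cutoff in runs (default 80; must be <= nRuns).
#' @param exclude character, feature names excluded from screening.
#' @param numTrees,mtry forest size per run (defaults as in
#'   [rfImportance()]).
#' @param seed master seed; run `k` derives its own seed from it.
#' @return a [ScreeningReport-class].
#' @export
borutaRankRuns <- function(X, y, nRuns = 100L, cutoff = 80L,
                           exclude = character(), numTrees = 500L,
                           mtry = NULL, seed = 1L) {
  if (nRuns < cutoff) stop("nRuns must be >= cutoff")
  excluded <- intersect(colnames(X), exclude)
  Xs <- X[, setdiff(colnames(X), excluded), drop = FALSE]
  p <- ncol(Xs)
  hist <- matrix(NA_real_, p, nRuns,
                 dimnames = list(colnames(Xs), NULL))
  below <- integer(p)
  rankSum <- numeric(p)
  for (k in seq_len(nRuns)) {
    Xaug <- shadowAugment(Xs, seed = derivedSeed(seed, 2L * k))
    imp <- rfImportance(Xaug, y, numTrees = numTrees, mtry = mtry,
                        seed = derivedSeed(seed, 2L * k + 1L))
    real <- imp[seq_len(p)]
    bestShadow <- max(imp[(p + 1L):(2L * p)])
    hist[, k] <- real
    below <- below + as.integer(real < bestShadow)
    rankSum <- rankSum + rank(-real, ties.method = "average")
  }
  decision <- ifelse(below >= cutoff, "remove", "keep")
  new("ScreeningReport",
      importanceHistory = hist,
      timesBelowBestShadow = below,
      decision = unname(decision),
      avgRank = rankSum / nRuns,
      excluded = excluded,
      nRuns = as.integer(nRuns),
      cutoff = as.integer(cutoff))
}

#' One-class SVM outlier filter
#'
#' Standardizes the feature matrix (zero mean, unit variance per column;
#' constant columns are left centred) and fits a radial-basis one-class
#' SVM with the stated parameters (gamma 0.001, support-vector fraction
#' lower bound nu = 0.03, convergence tolerance 1e-3). Rows with a
#' negative decision value are flagged as outliers; on clean data the
#' flagged fraction is approximately bounded by nu.
#'
#' @param X numeric feature matrix with >= 10 rows.
#' @param gamma RBF kernel width (default 0.001).
#' @param nu lower bound on the support-vector fraction (default 0.03).
#' @param tol convergence tolerance (default 1e-3).
#' @return logical inlier mask (`TRUE` = keep), with the fitted model in
#'   attribute `"model"`.
#' @export
ocsvmFilter <- function(X, gamma = 0.001, nu = 0.03, tol = 1e-3) {
  X <- as.matrix(X)
  if (nrow(X) < 10L)
    stop("need at least 10 rows to identify an outlier boundary")
  if (nu <= 0 || nu >= 1) stop("nu must be in (0, 1)")
  if (gamma <= 0) stop("gamma must be > 0")
  mu <- colMeans(X)
  s <- apply(X, 2L, sd)
  s[s < 1e-8] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, s, "/")
  fit <- e1071::svm(Z, y = NULL, type = "one-classification",
                    kernel = "radial", gamma = gamma, nu = nu,
                    tolerance = tol, scale = FALSE)
  pr <- predict(fit, Z, decision.values = TRUE)
  mask <- as.logical(pr)
  structure(mask, model = fit,
            decision = as.numeric(attr(pr, "decision.values")))
}
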