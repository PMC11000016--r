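#' Cross-validated nonlinear regression of a DDM parameter on connectivity
#'
#' Trains a one-hidden-layer feedforward network (weight-decay regularized;
#' small cohorts demand strong regularization) to predict one decision-model
#' parameter per subject from connectivity summaries (typically the mean
#' non-self linear and nonlinear connectivity), and evaluates it by k-fold
#' cross-validation. The reported goodness of fit is the normalized error:
#' the mean cross-validated squared estimation error divided by the mean
#' absolute value of the target, which removes the target's scale
#' (multiplying y by c > 0 scales the normalized error by c). The 95% CI is a
#' t-interval over the fold errors. Fold assignment is seeded and invariant
#' to subject ordering only through the seed; folds with fewer than 2 test
#' subjects are merged into the next fold (with a message).
#'
#' @param X numeric matrix, subjects x features.
#' @param y numeric target, one value per subject (a DDM parameter).
#' @param hiddenUnits hidden layer size (default 8).
#' @param folds number of CV folds (default 10; requires
#'   `length(y) >= folds`).
#' @param decay weight decay for [nnet::nnet()].
#' @param maxit training iteration cap.
#' @param seed integer seed (fold assignment and network initialization).
#' @param target,band,process metadata tags carried into the result.
#' @return list (RegressionResult): `target`, `band`, `process`,
#'   `normalized_error`, `ci95` (lo, hi), `fold_errors`.
#' @export
fitPredictCV <- function(X, y, hiddenUnits = 8, folds = 10, decay = 0.05,
                         maxit = 500, seed = 1, target = "", band = "",
                         process = "") {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (n < folds) stop("need at least as many subjects as folds")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, 808L))
  fold <- sample(rep(seq_len(folds), length.out = n))
  # merge undersized folds into the following fold
  repeat {
    sizes <- tabulate(fold, folds)
    small <- which(sizes > 0 & sizes < 2)
    if (!length(small)) break
    k <- small[1]
    nxt <- if (k < folds) k + 1 else k - 1
    message("fold ", k, " has < 2 test subjects; merged into fold ", nxt)
    fold[fold == k] <- nxt
  }
  meanAbsY <- mean(abs(y))
  if (meanAbsY == 0) stop("target has zero mean absolute value")
  foldErr <- numeric(0)
  for (k in sort(unique(fold))) {
    test <- which(fold == k)
    train <- setdiff(seq_len(n), test)
    mu <- colMeans(X[train, , drop = FALSE])
    sdv <- apply(X[train, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
    set.seed(childSeed(seed, 909L, k))
    net <- nnet::nnet(Xs[train, , drop = FALSE], matrix(y[train]),
                      size = hiddenUnits, linout = TRUE, decay = decay,
                      maxit = maxit, trace = FALSE)
    pred <- as.numeric(predict(net, Xs[test, , drop = FALSE]))
    foldErr <- c(foldErr, mean((pred - y[test])^2) / meanAbsY)
  }
  nf <- length(foldErr)
  m <- mean(foldErr)
  se <- sd(foldErr) / sqrt(nf)
  ci <- m + c(-1, 1) * qt(0.975, nf - 1) * se
  ci[1] <- max(ci[1], 0)
  list(target = target, band = band, process = process,
       normalized_error = m, ci95 = ci, fold_errors = foldErr)
}

#' Compare two cross-validated regression results by CI overlap
#'
#' Two conditions differ significantly when their 95% confidence intervals of
#' the normalized prediction error do not overlap.
#'
#' @param resultA,resultB results from [fitPredictCV()] for the same target
#'   parameter.
#' @return logical: TRUE when the CIs are disjoint.
#' @export
compareConditions <- function(resultA, resultB) {
  if (!identical(resultA$target, resultB$target))
    stop("results target different parameters")
  a <- resultA$ci95; b <- resultB$ci95
  a[2] < b[1] || b[2] < a[1]
}
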