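test_that("lag embedding has the right shape and respects trial joints", {
  x <- matrix(rnorm(2 * 50), 2, 50)
  emb <- embedLags(x, 3)
  expect_equal(nrow(emb$X), 47)             # L - p rows
  expect_equal(ncol(emb$X), 6)              # M * p columns
  expect_equal(emb$Y[1, ], x[, 4])
  expect_equal(emb$X[1, ], c(x[, 3], x[, 2], x[, 1]))
  # two concatenated trials: no row mixes samples from both
  y <- matrix(rnorm(2 * 30), 2, 30)
  emb2 <- embedLags(list(x, y), 3)
  expect_equal(nrow(emb2$X), 47 + 27)
  expect_equal(emb2$Y[48, ], y[, 4])        # first row of trial 2
  expect_equal(emb2$X[48, ], c(y[, 3], y[, 2], y[, 1]))
  expect_error(embedLags(matrix(rnorm(4), 2, 2), 3), "exceed")
})

test_that("an AR(1) scalar series is reconstructed exactly by one lag", {
  set.seed(1)
  x <- matrix(0, 1, 200)
  for (n in 2:200) x[n] <- 0.7 * x[n - 1]
  x[1] <- 1; for (n in 2:200) x[n] <- 0.7 * x[n - 1]
  emb <- embedLags(x, 1)
  ahat <- solve(crossprod(emb$X), crossprod(emb$X, emb$Y))
  expect_equal(as.numeric(ahat), 0.7, tolerance = 1e-10)
})

test_that("on linear data the nonlinear path is not needed", {
  spec <- linearVARSpec()
  src <- genCoupledSources(spec, 1, 3000, seed = 3)
  half <- 1500
  train <- src$data[, 1:half, 1]
  test <- src$data[, (half + 1):3000, 1]
  full <- suppressWarnings(trainNCREANN(train, p = 2, hiddenUnits = 16,
                                        maxit = 250, restarts = 1, seed = 2))
  linOnly <- trainNCREANN(train, p = 2, hiddenUnits = 0, seed = 2)
  eFull <- predictNMVAR(full, test)$mseFull
  eLin <- predictNMVAR(linOnly, test)$mseFull
  expect_lt(abs(eFull - eLin) / eLin, 0.05) # held-out errors about equal
})

test_that("a square coupling is captured only by the full model", {
  src <- genCoupledSources(squareCouplingSpec(0.6), 1, 3000, seed = 5)
  half <- 1500
  train <- src$data[, 1:half, 1]
  test <- src$data[, (half + 1):3000, 1]
  full <- trainNCREANN(train, p = 1, hiddenUnits = 10, maxit = 300,
                       restarts = 2, seed = 4)
  linOnly <- trainNCREANN(train, p = 1, hiddenUnits = 0, seed = 4)
  expect_lt(predictNMVAR(full, test)$mseFull,
            0.9 * predictNMVAR(linOnly, test)$mseFull)
})

test_that("time-shuffled surrogates have no predictable structure", {
  spec <- linearVARSpec()
  src <- genCoupledSources(spec, 1, 2000, seed = 7)
  x <- src$data[, , 1]
  set.seed(8)
  xs <- x[, sample(ncol(x))]
  m <- trainNCREANN(xs, p = 2, hiddenUnits = 8, maxit = 150, restarts = 1,
                    seed = 1)
  expect_lt(predictNMVAR(m, xs)$r2, 0.05)
})

test_that("full-model training error never exceeds the linear-only error", {
  spec <- linearVARSpec()
  src <- genCoupledSources(spec, 1, 1500, seed = 9)
  x <- src$data[, , 1]
  full <- suppressWarnings(trainNCREANN(x, p = 2, hiddenUnits = 16,
                                        maxit = 200, restarts = 1, seed = 3))
  linOnly <- trainNCREANN(x, p = 2, hiddenUnits = 0, seed = 3)
  expect_lte(predictNMVAR(full, x)$mseFull,
             predictNMVAR(linOnly, x)$mseFull + 1e-6)
})

test_that("linear connectivity recovers a single planted edge", {
  A1 <- matrix(0, 2, 2); diag(A1) <- 0.3; A1[2, 1] <- 0.8
  A2 <- matrix(0, 2, 2)
  spec <- couplingSpec(2, 2, list(A1, A2), noiseSd = 1)
  src <- genCoupledSources(spec, 1, 3000, seed = 11)
  m <- trainNCREANN(src$data[, , 1], p = 2, hiddenUnits = 8, maxit = 200,
                    restarts = 1, seed = 2)
  lC <- linearConnectivity(m)
  expect_gt(lC[1, 2], lC[2, 1])
  expect_lte(lC[2, 1], 0.2 * lC[1, 2])      # off-pattern entry small
})

test_that("connectivity is equivariant under node relabeling", {
  spec <- linearVARSpec()
  src <- genCoupledSources(spec, 1, 2000, seed = 13)
  x <- src$data[, , 1]
  perm <- c(3, 5, 1, 2, 4)
  m1 <- trainNCREANN(x, p = 2, hiddenUnits = 0, seed = 1)
  m2 <- trainNCREANN(x[perm, ], p = 2, hiddenUnits = 0, seed = 1)
  expect_equal(linearConnectivity(m2), linearConnectivity(m1)[perm, perm],
               tolerance = 1e-8)
})

test_that("NC is near zero on linear data and finite on all-zero input", {
  spec <- linearVARSpec()
  src <- genCoupledSources(spec, 1, 3000, seed = 15)
  x <- src$data[, , 1]
  m <- suppressWarnings(trainNCREANN(x, p = 2, hiddenUnits = 20, maxit = 250,
                                     restarts = 1, seed = 5))
  lC <- linearConnectivity(m)
  NC <- nonlinearConnectivity(m, x)
  off <- row(lC) != col(lC)
  expect_lt(median(NC[off]), 0.25 * median(lC[off]))
  NC0 <- nonlinearConnectivity(m, matrix(m@center, 5, 60))
  expect_true(all(is.finite(NC0)))
})

test_that("NC points from the nonlinear source to its target", {
  src <- genCoupledSources(squareCouplingSpec(0.6), 1, 3000, seed = 17)
  cm <- estimateConnectivity(src$data[, , 1], p = 1, hiddenUnits = 10,
                             maxit = 300, restarts = 2, seed = 3)
  NC <- nonlinC(cm)
  expect_gt(NC[1, 2], NC[2, 1])
})

test_that("order selection finds the generating order", {
  A1 <- diag(c(0.4, 0.4)); A2 <- diag(c(-0.3, 0.3))
  A3 <- matrix(c(0, 0.35, 0.3, 0), 2, 2)
  spec <- couplingSpec(2, 3, list(A1, A2, A3), noiseSd = 1)
  hits <- 0
  for (s in 1:5) {
    src <- genCoupledSources(spec, 1, 2000, seed = 20 + s)
    sel <- selectOrder(src$data[, , 1], pMax = 6)
    hits <- hits + (abs(sel$pBIC - 3) <= 1)
    expect_gte(sel$pAIC, sel$pBIC)          # AIC penalizes less
  }
  expect_gte(hits, 4)
  # white noise prefers order 0 or 1
  set.seed(30)
  wn <- matrix(rnorm(2 * 2000), 2, 2000)
  expect_lte(selectOrder(wn, pMax = 6)$pBIC, 1)
})

test_that("normalization maps the set to [0,1] with max exactly 1", {
  set.seed(31)
  mk <- function(mx) {
    l <- matrix(runif(9), 3, 3); l[1, 2] <- mx
    ConnectivityMatrix(l, matrix(runif(9), 3, 3), band = "theta")
  }
  set1 <- list(mk(2.0), mk(1.4))
  norm <- normalizeConnectivity(set1)
  offVals <- unlist(lapply(norm, function(cm) {
    m <- linC(cm); m[row(m) != col(m)]
  }))
  expect_equal(max(offVals), 1)
  expect_true(all(offVals >= 0 & offVals <= 1))
  expect_true(all(vapply(norm, isNormalized, logical(1))))
  # relative ordering preserved
  r1 <- rank(linC(set1[[1]])[row(linC(set1[[1]])) != col(linC(set1[[1]]))])
  r2 <- rank(linC(norm[[1]])[row(linC(norm[[1]])) != col(linC(norm[[1]]))])
  expect_equal(r1, r2)
  # lC and NC normalized independently
  set2 <- lapply(set1, function(cm)
    ConnectivityMatrix(linC(cm), 10 * nonlinC(cm), band = cm@band))
  expect_equal(linC(normalizeConnectivity(set2)[[1]]), linC(norm[[1]]))
  # idempotent
  norm2 <- normalizeConnectivity(norm)
  expect_equal(linC(norm2[[1]]), linC(norm[[1]]))
  expect_error(normalizeConnectivity(list(
    ConnectivityMatrix(matrix(0, 2, 2), matrix(0, 2, 2)))), "all-zero")
})

test_that("non-self averaging ignores the diagonal", {
  l <- matrix(0, 2, 2); l[1, 2] <- 0.4; l[2, 1] <- 0.6; diag(l) <- 5
  n <- l / 2
  cm <- ConnectivityMatrix(l, n)
  av <- averageNonself(cm)
  expect_equal(av$lC, 0.5)
  expect_equal(av$NC, 0.25)
  # perturbing the diagonal changes nothing
  l2 <- l; diag(l2) <- 100
  expect_equal(averageNonself(ConnectivityMatrix(l2, n))$lC, 0.5)
  # constant matrix averages to the constant
  cmc <- ConnectivityMatrix(matrix(0.3, 3, 3), matrix(0.3, 3, 3))
  expect_equal(averageNonself(cmc)$lC, 0.3)
  expect_error(averageNonself(ConnectivityMatrix(matrix(1, 1, 1),
                                                 matrix(1, 1, 1))), "2 nodes")
})

test_that("training is deterministic given the seed", {
  src <- genCoupledSources(squareCouplingSpec(0.5), 1, 800, seed = 40)
  m1 <- trainNCREANN(src$data[, , 1], p = 1, hiddenUnits = 6, maxit = 100,
                     restarts = 1, seed = 9)
  m2 <- trainNCREANN(src$data[, , 1], p = 1, hiddenUnits = 6, maxit = 100,
                     restarts = 1, seed = 9)
  expect_identical(m1@A, m2@A)
  expect_identical(m1@W1, m2@W1)
})
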