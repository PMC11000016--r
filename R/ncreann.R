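#' Lag embedding of multivariate time series
#'
#' Builds the regression matrices of an order-p autoregressive model: each
#' row of `X` holds the p past samples of all M nodes (lag-major:
#' `x1(n-1) ... xM(n-1), x1(n-2) ... xM(n-p)`), each row of `Y` the current
#' sample. Trials are embedded independently, so no row spans a concatenation
#' joint.
#'
#' @param ts a nodes x time matrix, or a list of such matrices (trials), or a
#'   nodes x time x trials array.
#' @param p model order; every trial must be longer than p.
#' @return list with `X` (N x M*p), `Y` (N x M), `M`, `p`.
#' @export
embedLags <- function(ts, p) {
  trials <- asTrialList(ts)
  M <- nrow(trials[[1]])
  Xs <- list(); Ys <- list()
  for (tr in trials) {
    L <- ncol(tr)
    if (L <= p) stop("trial length must exceed the model order")
    n <- (p + 1):L
    Y <- t(tr[, n, drop = FALSE])
    X <- matrix(0, length(n), M * p)
    for (k in seq_len(p))
      X[, ((k - 1) * M + 1):(k * M)] <- t(tr[, n - k, drop = FALSE])
    Xs[[length(Xs) + 1]] <- X
    Ys[[length(Ys) + 1]] <- Y
  }
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys), M = M, p = as.integer(p))
}

asTrialList <- function(ts) {
  if (is.list(ts)) return(ts)
  if (is.matrix(ts)) return(list(ts))
  if (is.array(ts) && length(dim(ts)) == 3)
    return(lapply(seq_len(dim(ts)[3]), function(i) ts[, , i]))
  stop("ts must be a matrix, a list of matrices, or a 3-d array")
}

#' Train a nonlinear MVAR model (linear path + one-hidden-layer network)
#'
#' Fits `x(n) = A xp + W2 tanh(W1 xp + b1) + b2 + noise` by minimizing the
#' mean squared one-step-ahead error jointly over the linear and nonlinear
#' paths (full-batch quasi-Newton with analytic gradients). Node series are
#' standardized before training. The linear path is initialized at the
#' ordinary least-squares VAR solution and is unpenalized; the hidden path
#' starts with zero output weights and carries a small weight decay, biasing
#' the model toward the linear explanation so the nonlinear part only absorbs
#' structure the VAR cannot. With `hiddenUnits = 0` the fit reduces exactly
#' to the OLS VAR. Deterministic given `seed`; the best of `restarts` seeded
#' restarts is kept.
#'
#' @param ts series as accepted by [embedLags()].
#' @param p model order (default 10).
#' @param hiddenUnits hidden layer size (default `2 * M * p`).
#' @param decay L2 penalty on the hidden-path weights.
#' @param maxit optimizer iteration cap per restart.
#' @param restarts number of seeded restarts.
#' @param seed integer seed.
#' @param standardize z-score each node before training (recommended).
#' @return an [NMVARModel-class].
#' @export
trainNCREANN <- function(ts, p = 10, hiddenUnits = NULL, decay = 0.01,
                         maxit = 400, restarts = 3, seed = 1,
                         standardize = TRUE) {
  trials <- asTrialList(ts)
  M <- nrow(trials[[1]])
  ctr <- numeric(M); scl <- rep(1, M)
  if (standardize) {
    allDat <- do.call(cbind, trials)
    ctr <- rowMeans(allDat)
    scl <- apply(allDat, 1, sd)
    scl[scl == 0] <- 1
    trials <- lapply(trials, function(tr) (tr - ctr) / scl)
  }
  emb <- embedLags(trials, p)
  X <- emb$X; Y <- emb$Y
  N <- nrow(X); d <- ncol(X)
  H <- if (is.null(hiddenUnits)) 2L * M * as.integer(p) else
    as.integer(hiddenUnits)
  nPar <- M * d + H * d + H + M * H + M
  if (N < 10 * nPar && H > 0)
    warning(sprintf("only %d samples for %d parameters (< 10x)", N, nPar))

  # OLS VAR backbone (linear-path initialization and H = 0 shortcut)
  XtX <- crossprod(X) + 1e-10 * diag(d)
  A0 <- t(solve(XtX, crossprod(X, Y)))            # M x d
  if (H == 0L) {
    E0 <- Y - X %*% t(A0)
    return(newNMVAR(M, p, A0, matrix(0, 0, d), numeric(0),
                    matrix(0, M, 0), colMeans(Y) * 0,
                    ctr, scl, E0, mean(E0^2), TRUE, seed))
  }

  pack <- function(A, W1, b1, W2, b2) c(A, W1, b1, W2, b2)
  unpack <- function(th) {
    i <- 0
    A <- matrix(th[i + seq_len(M * d)], M, d); i <- i + M * d
    W1 <- matrix(th[i + seq_len(H * d)], H, d); i <- i + H * d
    b1 <- th[i + seq_len(H)]; i <- i + H
    W2 <- matrix(th[i + seq_len(M * H)], M, H); i <- i + M * H
    b2 <- th[i + seq_len(M)]
    list(A = A, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  objgrad <- function(th) {
    w <- unpack(th)
    Z <- X %*% t(w$W1)
    Z <- sweep(Z, 2, w$b1, `+`)
    Tn <- tanh(Z)
    E <- X %*% t(w$A) + Tn %*% t(w$W2) +
      matrix(w$b2, N, M, byrow = TRUE) - Y
    loss <- mean(E^2) / 2 + decay / 2 * (sum(w$W1^2) + sum(w$W2^2))
    gA <- crossprod(E, X) / N
    gb2 <- colMeans(E)
    gW2 <- crossprod(E, Tn) / N + decay * w$W2
    G <- (E %*% w$W2) * (1 - Tn^2)
    gW1 <- crossprod(G, X) / N + decay * w$W1
    gb1 <- colMeans(G)
    list(value = loss, grad = pack(gA, gW1, gb1, gW2, gb2))
  }
  fn <- function(th) objgrad(th)$value
  gr <- function(th) objgrad(th)$grad

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(childSeed(seed, 707L, r))
    th0 <- pack(A0,
                matrix(rnorm(H * d, sd = 1 / sqrt(d)), H, d),
                rnorm(H, sd = 0.1),
                matrix(0, M, H),            # zero output weights: start linear
                numeric(M))
    fit <- optim(th0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = 1e4))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  w <- unpack(best$par)
  Z <- sweep(X %*% t(w$W1), 2, w$b1, `+`)
  E <- X %*% t(w$A) + tanh(Z) %*% t(w$W2) +
    matrix(w$b2, N, M, byrow = TRUE) - Y
  newNMVAR(M, p, w$A, w$W1, w$b1, w$W2, w$b2, ctr, scl, E,
           best$value, best$convergence %in% c(0, 1), seed)
}

newNMVAR <- function(M, p, Alin, W1, b1, W2, b2, ctr, scl, E, loss,
                     converged, seed) {
  # identifiability of the fLin/fNonLin split: tanh units are linear near the
  # origin, so the hidden path's first-order term (its Jacobian at 0) is
  # reassigned to the linear path; the remaining nonlinear part has zero
  # slope at the operating point
  d <- M * p
  J0 <- if (nrow(W1) > 0) W2 %*% ((1 - tanh(b1)^2) * W1) else
    matrix(0, M, d)
  AlinEff <- Alin + J0
  A <- array(0, dim = c(M, M, p))
  for (k in seq_len(p)) A[, , k] <- AlinEff[, ((k - 1) * M + 1):(k * M)]
  new("NMVARModel", M = as.integer(M), p = as.integer(p), A = A,
      W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2), J0 = J0,
      center = ctr, scale = scl,
      sigma = apply(E, 2, sd), loss = loss,
      converged = converged, seed = as.integer(seed))
}

#' One-step-ahead predictions of an NMVAR model
#'
#' Mean squared one-step error of the full model and of its linear path
#' alone, on the given series (standardized with the model's training
#' scaling). The full model is nested above the linear path, so on training
#' data its error cannot exceed the linear-only error.
#'
#' @param model an [NMVARModel-class].
#' @param ts series as accepted by [embedLags()].
#' @return list with `mseFull`, `mseLinear`, `r2` (full model).
#' @export
predictNMVAR <- function(model, ts) {
  trials <- lapply(asTrialList(ts),
                   function(tr) (tr - model@center) / model@scale)
  emb <- embedLags(trials, model@p)
  Alin <- matrix(model@A, model@M, model@M * model@p)
  lin <- emb$X %*% t(Alin)
  full <- lin + matrix(model@b2, nrow(lin), model@M, byrow = TRUE)
  if (nrow(model@W1) > 0) {
    Tn <- tanh(sweep(emb$X %*% t(model@W1), 2, model@b1, `+`))
    # the hidden path's first-order term already lives in A
    full <- full + Tn %*% t(model@W2) - emb$X %*% t(model@J0)
  }
  mseF <- mean((full - emb$Y)^2)
  mseL <- mean((lin - emb$Y)^2)
  list(mseFull = mseF, mseLinear = mseL,
       r2 = 1 - mseF / mean(scale(emb$Y, scale = FALSE)^2))
}

#' Linear directed connectivity from the model's linear path
#'
#' `lC[i, j]` = mean over lags of the absolute linear weight by which node i's
#' past enters node j's prediction. Equivariant under node relabeling.
#'
#' @param model an [NMVARModel-class].
#' @return nonnegative M x M matrix, entry `[i, j]` = influence i -> j.
#' @export
linearConnectivity <- function(model) {
  stopifnot(is(model, "NMVARModel"))
  # A[j, i, k]: effect of i on j at lag k -> lC[i, j]
  t(apply(abs(model@A), c(1, 2), mean))
}

#' Nonlinear directed connectivity by trajectory sensitivity
#'
#' `NC[i, j]` = mean over observed samples and lags of the absolute partial
#' derivative of the nonlinear path's output for node j with respect to node
#' i's lagged sample, evaluated along the trajectory (sensitivity-based
#' attribution). For a model trained on linear data the hidden path is
#' near-zero and so is NC; for an all-zero input the derivatives at 0 are
#' finite.
#'
#' @param model an [NMVARModel-class].
#' @param ts the series to evaluate along (typically the training series).
#' @param maxSamples sensitivity is averaged over at most this many evenly
#'   spaced embedded samples.
#' @return nonnegative M x M matrix, entry `[i, j]` = influence i -> j.
#' @export
nonlinearConnectivity <- function(model, ts, maxSamples = 2000) {
  stopifnot(is(model, "NMVARModel"))
  M <- model@M; p <- model@p
  if (nrow(model@W1) == 0) return(matrix(0, M, M))
  trials <- lapply(asTrialList(ts),
                   function(tr) (tr - model@center) / model@scale)
  emb <- embedLags(trials, p)
  X <- emb$X
  if (nrow(X) > maxSamples)
    X <- X[round(seq(1, nrow(X), length.out = maxSamples)), , drop = FALSE]
  Tn <- tanh(sweep(X %*% t(model@W1), 2, model@b1, `+`))
  Dn <- 1 - Tn^2                               # N x H
  accum <- matrix(0, M, ncol(X))
  for (n in seq_len(nrow(X))) {
    J <- model@W2 %*% (Dn[n, ] * model@W1) - model@J0   # M x (M*p)
    accum <- accum + abs(J)
  }
  accum <- accum / nrow(X)
  NC <- matrix(0, M, M)
  for (k in seq_len(p))
    NC <- NC + t(accum[, ((k - 1) * M + 1):(k * M), drop = FALSE])
  NC / p
}

#' Estimate connectivity matrices from source signals
#'
#' Convenience wrapper: trains the model and extracts both measures.
#'
#' @inheritParams trainNCREANN
#' @param band,process,nodeNames metadata tags for the result.
#' @return a [ConnectivityMatrix-class] with the fitted model in attribute
#'   `"model"`.
#' @export
estimateConnectivity <- function(ts, p = 10, hiddenUnits = NULL,
                                 decay = 0.01, maxit = 400, restarts = 3,
                                 seed = 1, band = "", process = "",
                                 nodeNames = NULL) {
  model <- trainNCREANN(ts, p = p, hiddenUnits = hiddenUnits, decay = decay,
                        maxit = maxit, restarts = restarts, seed = seed)
  cm <- ConnectivityMatrix(linearConnectivity(model),
                           nonlinearConnectivity(model, ts),
                           band = band, process = process,
                           nodeNames = nodeNames)
  attr(cm, "model") <- model
  cm
}

#' Autoregressive order selection by information criteria
#'
#' Fits OLS VAR backbones of order 0..pMax on a common effective sample (all
#' series embedded at pMax) and computes the multivariate Akaike and Schwarz
#' criteria `log det(Sigma) + penalty * p M^2 / N`. AIC penalizes less, so its
#' minimizer is never below BIC's.
#'
#' @param ts series as accepted by [embedLags()].
#' @param pMax largest order considered.
#' @return list with `aic`, `bic` (per-order criterion values), `pAIC`,
#'   `pBIC`, and `recommended` (the BIC minimizer).
#' @export
selectOrder <- function(ts, pMax = 20) {
  trials <- asTrialList(ts)
  M <- nrow(trials[[1]])
  embFull <- embedLags(trials, pMax)
  X <- embFull$X; Y <- embFull$Y
  N <- nrow(Y)
  ldet <- function(E) {
    S <- crossprod(E) / N
    determinant(S + 1e-12 * diag(M))$modulus[1]
  }
  aic <- bic <- numeric(pMax + 1)
  for (p in 0:pMax) {
    E <- if (p == 0) {
      sweep(Y, 2, colMeans(Y))
    } else {
      Xp <- X[, seq_len(M * p), drop = FALSE]
      Y - Xp %*% solve(crossprod(Xp) + 1e-10 * diag(M * p),
                       crossprod(Xp, Y))
    }
    k <- p * M^2
    aic[p + 1] <- ldet(E) + 2 * k / N
    bic[p + 1] <- ldet(E) + log(N) * k / N
  }
  list(aic = aic, bic = bic,
       pAIC = which.min(aic) - 1L, pBIC = which.min(bic) - 1L,
       recommended = which.min(bic) - 1L)
}

#' Normalize a subject's connectivity matrices to [0, 1]
#'
#' Divides every linear matrix in the set by the maximum non-self linear
#' value across all bands and conditions of the set, and independently every
#' nonlinear matrix by the maximum non-self nonlinear value, so each measure
#' ranges in [0, 1] with at least one non-self entry equal to 1 across the
#' set. Monotone: relative ordering of entries is preserved. Idempotent.
#'
#' @param connList list of [ConnectivityMatrix-class] objects (one subject's
#'   band x condition set).
#' @return the same list, normalized.
#' @export
normalizeConnectivity <- function(connList) {
  stopifnot(length(connList) >= 1)
  offMax <- function(get) max(vapply(connList, function(cm) {
    m <- get(cm)
    off <- row(m) != col(m)
    if (any(off)) max(m[off]) else 0
  }, numeric(1)))
  maxL <- offMax(linC)
  maxN <- offMax(nonlinC)
  if (maxL <= 0 && maxN <= 0) stop("all-zero connectivity set")
  lapply(connList, function(cm) {
    ConnectivityMatrix(
      if (maxL > 0) linC(cm) / maxL else linC(cm),
      if (maxN > 0) nonlinC(cm) / maxN else nonlinC(cm),
      band = cm@band, process = cm@process, nodeNames = cm@nodeNames,
      normalized = TRUE)
  })
}

#' Mean non-self connectivity
#'
#' Mean of the off-diagonal entries, separately for the linear and nonlinear
#' measure; the diagonal (self-connections) is ignored.
#'
#' @param conn a [ConnectivityMatrix-class] with M >= 2 nodes.
#' @return list with `lC` and `NC` means.
#' @export
averageNonself <- function(conn) {
  stopifnot(is(conn, "ConnectivityMatrix"))
  m <- linC(conn)
  if (nrow(m) < 2) stop("need at least 2 nodes")
  off <- row(m) != col(m)
  list(lC = mean(linC(conn)[off]), NC = mean(nonlinC(conn)[off]))
}
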