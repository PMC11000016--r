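#' Coupling specification for the nonlinear MVAR source generator
#'
#' Defines an order-p nonlinear multivariate autoregressive system over M
#' nodes: per-lag linear coefficient matrices plus a list of nonlinear
#' coupling terms, each node driven by white (optionally band-limited)
#' innovations.
#'
#' @param M node count.
#' @param p model order.
#' @param linearCoeffs list of p numeric M x M matrices; entry `[j, i]` of the
#'   lag-k matrix is the linear effect of node i at lag k on node j. The
#'   companion matrix of the coefficients must have spectral radius < 1
#'   (stationarity).
#' @param nonlinearTerms list of terms, each
#'   `list(source =, target =, lag =, fun = "square"|"tanh"|"product",
#'   gain =)`. "square" adds `gain * x_source(n-lag)^2`, "tanh" adds
#'   `gain * tanh(x_source(n-lag))`, "product" adds
#'   `gain * x_source(n-lag) * x_target(n-lag)`.
#' @param noiseSd innovation SD, scalar or per node (> 0).
#' @param band optional band tag ("theta", "alpha", "beta") or length-2 Hz
#'   vector; when set, innovations are narrowband filtered white noise so the
#'   autoregressive recursion stays exact.
#' @return list of class `"CouplingSpec"`.
#' @export
couplingSpec <- function(M, p, linearCoeffs, nonlinearTerms = list(),
                         noiseSd = 1, band = NULL) {
  stopifnot(M >= 1, p >= 1, length(linearCoeffs) == p)
  for (Ak in linearCoeffs)
    stopifnot(is.matrix(Ak), nrow(Ak) == M, ncol(Ak) == M)
  noiseSd <- rep_len(noiseSd, M)
  if (any(noiseSd <= 0)) stop("noiseSd must be > 0")
  rho <- companionSpectralRadius(linearCoeffs)
  if (rho >= 1)
    stop(sprintf("linear coefficients are non-stationary (spectral radius %.3f >= 1)",
                 rho))
  for (term in nonlinearTerms) {
    stopifnot(term$source %in% seq_len(M), term$target %in% seq_len(M),
              term$lag %in% seq_len(p),
              term$fun %in% c("square", "tanh", "product"))
  }
  if (!is.null(band) && is.character(band)) {
    if (!band %in% names(FREQ_BANDS)) stop("unknown band tag: ", band)
  }
  structure(list(M = as.integer(M), p = as.integer(p),
                 linearCoeffs = linearCoeffs,
                 nonlinearTerms = nonlinearTerms,
                 noiseSd = noiseSd, band = band),
            class = "CouplingSpec")
}

#' Spectral radius of the VAR companion matrix
#' @param linearCoeffs list of p M x M lag matrices.
#' @return largest eigenvalue modulus.
#' @export
companionSpectralRadius <- function(linearCoeffs) {
  p <- length(linearCoeffs)
  M <- nrow(linearCoeffs[[1]])
  comp <- matrix(0, M * p, M * p)
  comp[seq_len(M), ] <- do.call(cbind, linearCoeffs)
  if (p > 1)
    comp[(M + 1):(M * p), seq_len(M * (p - 1))] <- diag(M * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate coupled node time series from a nonlinear MVAR system
#'
#' Each trial is simulated independently from the recursion
#' `x(n) = f_lin(xp) + f_nonlin(xp) + noise`, with a burn-in discarded. The
#' ground-truth directed adjacency (which source->target pairs carry linear
#' and nonlinear coupling) is attached to the result.
#'
#' @param spec a [couplingSpec()].
#' @param nTrials number of trials.
#' @param trialLen samples per trial (after burn-in).
#' @param seed integer seed.
#' @param burnin samples discarded at the start of each trial.
#' @param sfreq sampling rate used for band-limited innovations (Hz).
#' @param overflowGuard simulation aborts with a diagnostic when any |x|
#'   exceeds this value (divergence).
#' @return list with `data` (array nodes x time x trials) and `groundTruth`
#'   (list with logical M x M `linear` and `nonlinear` adjacency, `[i, j]`
#'   meaning i -> j, plus the term list).
#' @export
genCoupledSources <- function(spec, nTrials, trialLen, seed = 1,
                              burnin = 200, sfreq = 256,
                              overflowGuard = 1e6) {
  stopifnot(inherits(spec, "CouplingSpec"), nTrials >= 1, trialLen > spec$p)
  M <- spec$M; p <- spec$p
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, 303L))
  total <- trialLen + burnin
  dat <- array(0, dim = c(M, trialLen, nTrials))
  for (tr in seq_len(nTrials)) {
    eps <- matrix(rnorm(M * total), nrow = M) * spec$noiseSd
    if (!is.null(spec$band)) {
      band <- if (is.character(spec$band)) FREQ_BANDS[[spec$band]] else spec$band
      for (m in seq_len(M)) {
        filtered <- firBandpass(eps[m, ], band, sfreq)
        # rescale so the innovation SD is preserved after band-limiting
        eps[m, ] <- filtered * (spec$noiseSd[m] / max(sd(filtered), 1e-12))
      }
    }
    x <- matrix(0, nrow = M, ncol = total)
    for (n in (p + 1):total) {
      xn <- eps[, n]
      for (k in seq_len(p)) xn <- xn + spec$linearCoeffs[[k]] %*% x[, n - k]
      for (term in spec$nonlinearTerms) {
        xs <- x[term$source, n - term$lag]
        contrib <- switch(term$fun,
          square  = term$gain * xs^2,
          tanh    = term$gain * tanh(xs),
          product = term$gain * xs * x[term$target, n - term$lag])
        xn[term$target] <- xn[term$target] + contrib
      }
      if (any(abs(xn) > overflowGuard))
        stop(sprintf(
          "simulation diverged at trial %d, sample %d (|x| > %g)",
          tr, n, overflowGuard))
      x[, n] <- xn
    }
    dat[, , tr] <- x[, (burnin + 1):total, drop = FALSE]
  }
  linAdj <- matrix(FALSE, M, M)
  for (k in seq_len(p)) linAdj <- linAdj | (t(spec$linearCoeffs[[k]]) != 0)
  nlAdj <- matrix(FALSE, M, M)
  for (term in spec$nonlinearTerms)
    nlAdj[term$source, term$target] <- TRUE
  list(data = dat,
       groundTruth = list(linear = linAdj, nonlinear = nlAdj,
                          terms = spec$nonlinearTerms,
                          M = M, p = p))
}

#' Project source time series to sensors as an EpochArray
#'
#' Forward model for testing beamforming: the sensor data of each trial is the
#' sum of the sources projected through their voxel rows of the leadfield,
#' plus white sensor noise. The default epoch window runs -2000..+2000 ms at
#' 256 Hz with both endpoints included (1025 samples); shorter source arrays
#' get a window of the same convention centred on the onset.
#'
#' @param sources array nodes x time x trials (e.g. from
#'   [genCoupledSources()]).
#' @param leadfield a [Leadfield-class] object.
#' @param sourceVoxels voxel index per source node (length = node count).
#' @param sensorNoiseSd white sensor noise SD.
#' @param sfreq sampling rate in Hz.
#' @param conditions optional per-trial condition labels.
#' @param seed integer seed for the sensor noise.
#' @return an [EpochArray-class].
#' @export
genSensorEpochs <- function(sources, leadfield, sourceVoxels,
                            sensorNoiseSd = 0, sfreq = 256,
                            conditions = NULL, seed = 1) {
  stopifnot(is(leadfield, "Leadfield"))
  d <- dim(sources)
  if (length(sourceVoxels) != d[1])
    stop("source count must equal length(sourceVoxels)")
  G <- gainMatrix(leadfield)[sourceVoxels, , drop = FALSE]  # sources x chans
  nChan <- ncol(G)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, 404L))
  sens <- array(0, dim = c(nChan, d[2], d[3]))
  for (tr in seq_len(d[3])) {
    sens[, , tr] <- crossprod(G, sources[, , tr]) +
      if (sensorNoiseSd > 0) sensorNoiseSd * matrix(rnorm(nChan * d[2]),
                                                    nChan) else 0
  }
  onset <- (d[2] + 1L) %/% 2L
  EpochArray(sens, sfreq = sfreq,
             times = (seq_len(d[2]) - onset) / sfreq,
             channelNames = channelNames(leadfield),
             channelPositions = channelPositions(leadfield),
             conditions = conditions, onsetSample = onset)
}
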