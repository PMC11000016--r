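test_that("FIR band-pass preserves passband and attenuates stopband", {
  sf <- 256
  tt <- seq(0, 8, by = 1 / sf)[-1]
  mk <- function(f) EpochArray(array(sin(2 * pi * f * tt),
                                     dim = c(1, length(tt), 1)), sfreq = sf)
  amp <- function(ep) {
    x <- epochData(ep)[1, 500:1500, 1]
    sqrt(2 * mean(x^2))
  }
  expect_equal(amp(bandpassFIR(mk(10), "alpha")), 1, tolerance = 0.01)
  expect_lt(20 * log10(amp(bandpassFIR(mk(20), "alpha"))), -40)
  expect_error(bandpassFIR(mk(10), c(10, 200)), "Nyquist")
})

test_that("filtering twice applies the squared response", {
  sf <- 256
  tt <- seq(0, 8, by = 1 / sf)[-1]
  # a tone at the band edge, where the single-pass gain is not ~1
  ep <- EpochArray(array(sin(2 * pi * 12.5 * tt),
                         dim = c(1, length(tt), 1)), sfreq = sf)
  amp <- function(e) sqrt(2 * mean(epochData(e)[1, 500:1500, 1]^2))
  a1 <- amp(bandpassFIR(ep, "alpha"))
  a2 <- amp(bandpassFIR(bandpassFIR(ep, "alpha"), "alpha"))
  expect_equal(a2, a1^2, tolerance = 0.02)
})

test_that("the common filter satisfies unit gain at every voxel", {
  lf <- makeLeadfield(64, 24, seed = 2)
  src <- array(rnorm(2 * 300 * 8), dim = c(2, 300, 8))
  ep <- genSensorEpochs(src, lf, c(1, 64), sensorNoiseSd = 0.1, seed = 4)
  filt <- lcmvCommonFilter(ep, lf, reg = 0.05)
  ug <- rowSums(filterWeights(filt) * gainMatrix(lf))
  expect_lt(max(abs(ug - 1)), 1e-10)
})

test_that("a single simulated source is localized at its voxel", {
  lf <- makeLeadfield(64, 24, seed = 3)
  src <- array(rnorm(1 * 400 * 10), dim = c(1, 400, 10))
  ep <- genSensorEpochs(src, lf, 22, sensorNoiseSd = 0.05, seed = 5)
  filt <- lcmvCommonFilter(ep, lf)
  S <- reconstructSources(filt, ep)
  pw <- apply(S, 1, function(x) mean(x^2))
  expect_equal(which.max(pw), 22L)
})

test_that("two uncorrelated sources are both recovered", {
  lf <- makeLeadfield(64, 24, seed = 6)
  set.seed(8)
  src <- array(rnorm(2 * 400 * 12) * 5, dim = c(2, 400, 12))
  ep <- genSensorEpochs(src, lf, c(1, 64), sensorNoiseSd = 0.05, seed = 7)
  filt <- lcmvCommonFilter(ep, lf)
  S <- reconstructSources(filt, ep)
  pw <- apply(S, 1, function(x) mean(x^2))
  expect_setequal(order(-pw)[1:2], c(1, 64))
  # cross-talk: reconstructed series at voxel 1 tracks source 1, not source 2
  s1 <- as.vector(S[1, , ]); s64 <- as.vector(S[64, , ])
  x1 <- as.vector(src[1, , ]); x2 <- as.vector(src[2, , ])
  expect_gt(abs(cor(s1, x1)), 0.9)
  crossTalk <- (cor(s1, x2) / cor(s1, x1))^2
  expect_lt(10 * log10(crossTalk), -20)
  expect_lt(10 * log10((cor(s64, x1) / cor(s64, x2))^2), -20)
})

test_that("source gating contrast behaves on planted and null effects", {
  expect_equal(sourceGatingContrast(1:5, 1:5), rep(0, 5))
  # linearity on 1-d activity maps
  a <- runif(6); b <- runif(6)
  expect_equal(sourceGatingContrast(2 * a, 2 * b),
               2 * sourceGatingContrast(a, b))
  # planted switch-only source has the maximal per-voxel power effect
  lf <- makeLeadfield(27, 16, seed = 9)
  src <- array(rnorm(1 * 300 * 6) * 3, dim = c(1, 300, 6))
  epS <- genSensorEpochs(src, lf, 14, sensorNoiseSd = 0.05, seed = 1)
  epN <- genSensorEpochs(src * 0, lf, 14, sensorNoiseSd = 0.05, seed = 2)
  filt <- lcmvCommonFilter(epS, lf)
  eff <- sourceGatingContrast(reconstructSources(filt, epS),
                              reconstructSources(filt, epN))
  expect_equal(which.max(abs(eff)), 14L)
  expect_error(sourceGatingContrast(1:5, 1:4), "do not match")
})

test_that("top-percentile voxel selection follows ceil and tie rules", {
  eff <- seq_len(64) / 64
  expect_equal(selectTopVoxels(eff, pct = 1), 64L)   # ceil(0.64) = 1 voxel
  expect_equal(length(selectTopVoxels(runif(200), pct = 1)), 2L)
  expect_equal(selectTopVoxels(c(0.5, -0.9, 0.3), pct = 40),
               c(2L, 1L))                            # |effect| ordering
  expect_equal(selectTopVoxels(c(0.5, 0.5, 0.1), pct = 33), 1L)  # tie: index
  # permutation invariance
  eff2 <- runif(50)
  perm <- sample(50)
  selPerm <- selectTopVoxels(eff2[perm], pct = 10)
  expect_setequal(perm[selPerm], selectTopVoxels(eff2, pct = 10))
  expect_error(selectTopVoxels(numeric(0)), "empty")
})

test_that("DBSCAN separates groups, drops singletons, ignores ordering", {
  pts <- rbind(cbind(runif(5), runif(5), 0),
               cbind(runif(6) + 50, runif(6), 0),
               c(200, 200, 0))               # far singleton
  db <- dbscanCluster(pts, eps = 2, minPts = 2)
  expect_equal(nrow(db$clusters), 2)
  expect_equal(db$assignment[12], 0L)        # noise, excluded
  expect_true(all(db$clusters$n_voxels >= 2))
  perm <- sample(nrow(pts))
  db2 <- dbscanCluster(pts[perm, ], eps = 2, minPts = 2)
  # same partition up to label names
  lab1 <- db$assignment[perm]
  agree <- table(lab1, db2$assignment)
  expect_true(all(rowSums(agree > 0) == 1) && all(colSums(agree > 0) == 1))
})

test_that("DBSCAN with minPts = 2 matches the eps-graph components oracle", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(8:25, 1)
    pts <- matrix(runif(n * 3, 0, 6), ncol = 3)
    eps <- runif(1, 0.5, 2)
    db <- dbscanCluster(pts, eps = eps, minPts = 2)
    D <- as.matrix(dist(pts))
    g <- igraph::graph_from_adjacency_matrix(D <= eps & D > 0,
                                             mode = "undirected")
    comp <- unname(igraph::components(g)$membership)
    comp[tabulate(comp)[comp] < 2] <- 0      # singletons are noise
    mine <- db$assignment
    # identical partitions up to relabeling
    expect_equal(mine == 0, comp == 0)
    keep <- mine != 0
    if (any(keep)) {
      agree <- table(mine[keep], comp[keep])
      expect_true(all(rowSums(agree > 0) == 1) &&
                    all(colSums(agree > 0) == 1))
    }
  }
})

test_that("cluster signal extraction subtracts baseline and crops", {
  # hand-checked 3-sample toy, one voxel
  vts <- array(c(1, 2, 3), dim = c(1, 3, 1))
  base <- matrix(c(0.5, 1, 1.5), 1, 3)
  times <- c(-0.1, 0, 0.1)
  sig <- extractClusterSignals(vts, list(1L), base, times,
                               window = c(-0.5, 1.5))
  expect_equal(as.vector(sig[[1]]$data), c(0.5, 1, 1.5))
  # switch identical to nonswitch mean -> zero signal
  sig0 <- extractClusterSignals(array(base, dim = c(1, 3, 1)), list(1L),
                                base, times)
  expect_true(all(sig0[[1]]$data == 0))
  # -500..1500 ms at 256 Hz crops to 512 samples (half-open window)
  times2 <- (seq_len(1025) - 513) / 256
  vts2 <- array(rnorm(2 * 1025 * 3), dim = c(2, 1025, 3))
  base2 <- matrix(0, 2, 1025)
  sig2 <- extractClusterSignals(vts2, list(c(1L, 2L)), base2, times2)
  expect_equal(nrow(sig2[[1]]$data), 512)
  expect_error(extractClusterSignals(vts2, list(5L), base2, times2),
               "outside")
})

test_that("the full source pipeline recovers two planted clusters", {
  lf <- makeLeadfield(64, 24, seed = 10)
  vox <- voxelPositions(lf)
  srcVox <- c(1, 64)
  set.seed(3)
  src <- array(rnorm(2 * 300 * 15) * 5, dim = c(2, 300, 15))
  epS <- genSensorEpochs(src, lf, srcVox, sensorNoiseSd = 0.2, seed = 1)
  epN <- genSensorEpochs(src * 0, lf, srcVox, sensorNoiseSd = 0.2, seed = 2)
  filt <- lcmvCommonFilter(epS, lf)
  eff <- sourceGatingContrast(reconstructSources(filt, epS),
                              reconstructSources(filt, epN))
  sel <- selectTopVoxels(eff, pct = 10)
  db <- dbscanCluster(vox[sel, , drop = FALSE], eps = 1.5, minPts = 2)
  expect_equal(nrow(db$clusters), 2)
  cent <- as.matrix(db$clusters[, c("cx", "cy", "cz")])
  dTrue <- pmin(sqrt(rowSums((cent - vox[rep(1, 2), ])^2)),
                sqrt(rowSums((cent - vox[rep(64, 2), ])^2)))
  expect_true(all(dTrue <= 1.5))
})
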