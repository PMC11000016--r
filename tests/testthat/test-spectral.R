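mkSinusoidEpochs <- function(freq, amp = 1, sfreq = 128, dur = 4,
                             nTrials = 2) {
  tt <- seq(0, dur, by = 1 / sfreq)[-1]
  sig <- array(rep(amp * sin(2 * pi * freq * tt), nTrials),
               dim = c(1, length(tt), nTrials))
  EpochArray(sig, sfreq = sfreq)
}

test_that("a pure sinusoid peaks at its own frequency", {
  tf <- morletTFR(mkSinusoidEpochs(10), freqs = seq(5, 20, by = 0.5))
  prof <- apply(tfrPower(tf)[1, 1, , ], 1, mean, na.rm = TRUE)
  expect_equal(tfrFreqs(tf)[which.max(prof)], 10)
})

test_that("doubling the amplitude adds ~6.02 dB over an unchanged baseline", {
  # amplitude steps up 2x after onset; baseline window is pre-onset
  sf <- 128; tt <- seq(-2, 2, by = 1 / sf)
  amp <- ifelse(tt < 0, 1, 2)
  sig <- array(amp * sin(2 * pi * 10 * tt), dim = c(1, length(tt), 1))
  ep <- EpochArray(sig, sfreq = sf, times = tt)
  tf <- dbBaseline(morletTFR(ep, freqs = 10), window = c(-1.5, -0.5))
  post <- tfrPower(tf)[1, 1, 1, tt > 0.5 & tt < 1.5]
  expect_equal(mean(post, na.rm = TRUE), 20 * log10(2), tolerance = 0.15)
})

test_that("stationary signals are ~0 dB after baseline normalization", {
  set.seed(4)
  sig <- array(rnorm(1 * 512 * 6), dim = c(1, 512, 6))
  ep <- EpochArray(sig, sfreq = 128)
  tf <- dbBaseline(morletTFR(ep, freqs = seq(10, 20, 2)),
                   window = c(-0.5, 0))
  pw <- tfrPower(tf)
  expect_lt(abs(mean(pw, na.rm = TRUE)), 1)
  # baseline window averages to ~0 dB (up to the log-of-mean Jensen bias)
  sel <- epochTimes(ep) >= -0.5 & epochTimes(ep) <= 0
  expect_lt(abs(mean(pw[1, 1, , sel], na.rm = TRUE)), 1)
})

test_that("a 10x power step reads as 10 dB", {
  sf <- 128; tt <- seq(-2, 2, by = 1 / sf)
  amp <- ifelse(tt < 0, 1, sqrt(10))
  sig <- array(amp * sin(2 * pi * 12 * tt), dim = c(1, length(tt), 1))
  ep <- EpochArray(sig, sfreq = sf, times = tt)
  tf <- dbBaseline(morletTFR(ep, freqs = 12), window = c(-1.5, -0.5))
  post <- tfrPower(tf)[1, 1, 1, tt > 0.5 & tt < 1.5]
  expect_equal(mean(post, na.rm = TRUE), 10, tolerance = 0.5)
})

test_that("band definitions partition 4-30 Hz and average correctly", {
  freqs <- seq(1, 30, by = 0.5)
  inTheta <- freqs >= 4 & freqs <= 7
  inAlpha <- freqs >= 8 & freqs <= 12
  inBeta <- freqs >= 13 & freqs <= 30
  expect_equal(sum(inTheta), 7)             # 4.0 ... 7.0 at 0.5-Hz steps
  expect_false(any(inTheta & inAlpha) || any(inAlpha & inBeta))
  # every integer frequency from 4 to 30 Hz belongs to exactly one band
  ints <- freqs[freqs >= 4 & freqs == round(freqs)]
  expect_true(all((ints >= 4 & ints <= 7) | (ints >= 8 & ints <= 12) |
                    (ints >= 13 & ints <= 30)))
  # averaging a constant returns the constant
  pw <- array(3.5, dim = c(1, 2, length(freqs), 10))
  tf <- new("TFR", power = pw, freqs = freqs, times = seq_len(10) / 10,
            conditionNames = "c", channelNames = c("a", "b"),
            baselineWindow = c(NA_real_, NA_real_), dbNormalized = TRUE)
  expect_true(all(bandAverage(tf, "theta") == 3.5))
  expect_error(bandAverage(tf, c(40, 50)), "no analysis frequencies")
})

test_that("edge samples where the wavelet overruns the epoch are masked", {
  ep <- mkSinusoidEpochs(8, dur = 2)
  tf <- morletTFR(ep, freqs = c(4, 16))
  pw4 <- tfrPower(tf)[1, 1, 1, ]
  pw16 <- tfrPower(tf)[1, 1, 2, ]
  expect_gt(sum(is.na(pw4)), sum(is.na(pw16)))  # longer wavelet, wider mask
  expect_true(is.na(pw4[1]) && is.na(pw4[length(pw4)]))
  # epoch shorter than the wavelet at 1 Hz is fully masked with a warning
  expect_warning(tfLow <- morletTFR(ep, freqs = c(1, 16)), "fully masked")
  expect_true(all(is.na(tfrPower(tfLow)[1, 1, 1, ])))
})

test_that("identical conditions produce no clusters and p = 1", {
  set.seed(6)
  A <- array(rnorm(8 * 3 * 20), dim = c(8, 3, 20))
  adj <- channelAdjacency(cbind(1:3, 0, 0))
  res <- clusterPermTest(A, A, adj, nPerm = 100, seed = 1)
  expect_length(res$clusters, 0)
  expect_equal(res$p, 1)
})

test_that("Monte-Carlo p-values are bounded below by 1/(nPerm+1)", {
  set.seed(7)
  A <- array(rnorm(8 * 3 * 20, mean = 2), dim = c(8, 3, 20))
  B <- array(rnorm(8 * 3 * 20), dim = c(8, 3, 20))
  adj <- channelAdjacency(cbind(1:3, 0, 0))
  res <- clusterPermTest(A, B, adj, nPerm = 200, seed = 2)
  expect_gte(res$p, 1 / 201)
  expect_true(all(vapply(res$clusters, `[[`, numeric(1), "p") <= 1))
})

test_that("clusters form a partition of suprathreshold points", {
  set.seed(8)
  A <- array(rnorm(10 * 4 * 25, sd = 1), dim = c(10, 4, 25))
  B <- A + array(rnorm(10 * 4 * 25, 0.3), dim = c(10, 4, 25))
  adj <- channelAdjacency(cbind(1:4, 0, 0))
  res <- clusterPermTest(A, B, adj, nPerm = 100, seed = 3)
  allPts <- do.call(rbind, lapply(res$clusters, `[[`, "points"))
  if (!is.null(allPts))
    expect_equal(nrow(allPts), nrow(unique(allPts)))
})

test_that("a planted effect is detected and covers most of its patch", {
  set.seed(9)
  nS <- 12; nC <- 4; nT <- 40
  A <- array(rnorm(nS * nC * nT), dim = c(nS, nC, nT))
  B <- array(rnorm(nS * nC * nT), dim = c(nS, nC, nT))
  patchT <- 11:30
  A[, , patchT] <- A[, , patchT] + 1.0      # effect on all 4 channels
  adj <- channelAdjacency(cbind(1:nC, 0, 0))
  res <- clusterPermTest(A, B, adj, nPerm = 300, seed = 4)
  expect_gt(length(res$clusters), 0)
  top <- res$clusters[[1]]
  expect_true(top$significant)
  inPatch <- top$points[, "time"] %in% patchT
  expect_gt(sum(inPatch), 0.5 * nC * length(patchT))
})

test_that("permutation p-values are invariant to channel relabeling", {
  set.seed(10)
  nS <- 8; nC <- 4; nT <- 15
  A <- array(rnorm(nS * nC * nT), dim = c(nS, nC, nT))
  B <- array(rnorm(nS * nC * nT, 0.4), dim = c(nS, nC, nT))
  pos <- cbind(1:nC, 0, 0)
  adj <- channelAdjacency(pos)
  res1 <- clusterPermTest(A, B, adj, nPerm = 200, seed = 5)
  perm <- c(3, 1, 4, 2)
  res2 <- clusterPermTest(A[, perm, ], B[, perm, ],
                          adj[perm, perm], nPerm = 200, seed = 5)
  expect_equal(sort(vapply(res1$clusters, `[[`, numeric(1), "p")),
               sort(vapply(res2$clusters, `[[`, numeric(1), "p")))
})
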