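#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every channel x trial with complex Morlet wavelets and averages
#' the single-trial power per condition. The wavelet at frequency f has
#' `width` cycles (Gaussian SD `width / (2 pi f)` seconds) and is truncated at
#' `gaussLen` SDs on each side; these are the common toolbox readings of
#' "width" and "length" for Morlet parameters. Samples whose wavelet overruns
#' the epoch (half the wavelet length at each edge) are masked as NA - at low
#' frequencies the wavelet can exceed the whole epoch, in which case the row
#' is fully masked with a warning.
#'
#' @param epochs an [EpochArray-class].
#' @param freqs analysis frequencies in Hz (default 1-30 Hz in 0.5-Hz steps).
#' @param width wavelet width in cycles.
#' @param gaussLen Gaussian support half-length in SD units.
#' @return a [TFR-class] with raw (not yet baseline-normalized) power,
#'   condition x channel x frequency x time.
#' @export
morletTFR <- function(epochs, freqs = seq(1, 30, by = 0.5), width = 5.5,
                      gaussLen = 3) {
  stopifnot(is(epochs, "EpochArray"))
  sf <- samplingRate(epochs)
  if (sf < 2 * max(freqs))
    stop("sampling rate must be at least twice the maximum frequency")
  dat <- epochData(epochs)
  d <- dim(dat)
  conds <- unique(conditionLabels(epochs))
  nT <- d[2]
  # one big matrix time x (channel*trial); FFT once, reuse across frequencies
  sig <- matrix(aperm(dat, c(2, 1, 3)), nrow = nT)
  nPad <- stats::nextn(2 * nT, 2)
  SIG <- mvfft(rbind(sig, matrix(0, nPad - nT, ncol(sig))))
  power <- array(NA_real_, dim = c(length(conds), d[1], length(freqs), nT))
  condIdx <- lapply(conds, function(cc) which(conditionLabels(epochs) == cc))
  fullyMasked <- character(0)
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma <- width / (2 * pi * f)
    half <- floor(gaussLen * sigma * sf)
    nw <- 2 * half + 1
    if (nw >= nT) {
      fullyMasked <- c(fullyMasked, sprintf("%g Hz", f))
      next
    }
    tw <- (seq_len(nw) - half - 1) / sf
    w <- exp(2i * pi * f * tw) * exp(-tw^2 / (2 * sigma^2))
    w <- w / sum(abs(w))                     # amplitude normalization
    if (nw > nPad) next
    W <- fft(c(w, rep(0, nPad - nw)))
    conv <- mvfft(SIG * W, inverse = TRUE) / nPad
    # 'same' alignment: sample n of the signal is row n + half of the full
    # convolution
    pw <- abs(conv[(half + 1):(half + nT), , drop = FALSE])^2
    pw[c(seq_len(half), (nT - half + 1):nT), ] <- NA   # edge mask
    pwArr <- array(pw, dim = c(nT, d[1], d[3]))
    for (ci in seq_along(conds)) {
      avg <- apply(pwArr[, , condIdx[[ci]], drop = FALSE], c(1, 2), mean)
      power[ci, , fi, ] <- t(avg)
    }
  }
  if (length(fullyMasked))
    warning("wavelet longer than epoch; fully masked at: ",
            paste(fullyMasked, collapse = ", "))
  new("TFR", power = power, freqs = freqs, times = epochTimes(epochs),
      conditionNames = conds, channelNames = channelNames(epochs),
      baselineWindow = c(NA_real_, NA_real_), dbNormalized = FALSE)
}

#' Decibel baseline normalization of a TFR
#'
#' `10 * log10(power / mean baseline power)` per condition, channel and
#' frequency, with the baseline power averaged over `window` (default -200 to
#' 0 ms). After normalization the mean over the baseline window is 0 dB.
#'
#' @param tfr a [TFR-class] with raw power.
#' @param window length-2 numeric, baseline window in seconds.
#' @return the normalized [TFR-class].
#' @export
dbBaseline <- function(tfr, window = c(-0.2, 0)) {
  stopifnot(is(tfr, "TFR"))
  if (tfr@dbNormalized) stop("TFR is already dB-normalized")
  sel <- tfr@times >= window[1] & tfr@times <= window[2]
  if (!any(sel)) stop("baseline window lies outside the epoch")
  pw <- tfr@power
  d <- dim(pw)
  for (ci in seq_len(d[1])) for (ch in seq_len(d[2])) for (fi in seq_len(d[3])) {
    base <- mean(pw[ci, ch, fi, sel], na.rm = TRUE)
    if (is.nan(base)) next                     # fully masked row stays NA
    if (base <= 0) stop("zero baseline power; cannot dB-normalize")
    pw[ci, ch, fi, ] <- 10 * log10(pw[ci, ch, fi, ] / base)
  }
  new("TFR", power = pw, freqs = tfr@freqs, times = tfr@times,
      conditionNames = tfr@conditionNames, channelNames = tfr@channelNames,
      baselineWindow = as.numeric(window), dbNormalized = TRUE)
}

#' Average a TFR over a frequency band
#'
#' Band edges are inclusive: theta 4-7 Hz, alpha 8-12 Hz, beta 13-30 Hz
#' (which partition 4-30 Hz without overlap at the 0.5-Hz grid). Masked (NA)
#' bins are dropped from the average; time points masked at every band
#' frequency stay NA.
#'
#' @param tfr a [TFR-class].
#' @param band band tag ("theta", "alpha", "beta") or length-2 Hz vector.
#' @param condition optional condition label; when given, returns a
#'   channel x time matrix for that condition, otherwise a
#'   condition x channel x time array.
#' @return matrix or array of band power.
#' @export
bandAverage <- function(tfr, band, condition = NULL) {
  stopifnot(is(tfr, "TFR"))
  edges <- if (is.character(band)) {
    if (!band %in% names(FREQ_BANDS)) stop("unknown band tag: ", band)
    FREQ_BANDS[[band]]
  } else band
  sel <- tfr@freqs >= edges[1] & tfr@freqs <= edges[2]
  if (!any(sel)) stop("band contains no analysis frequencies")
  out <- apply(tfr@power[, , sel, , drop = FALSE], c(1, 2, 4), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  if (!is.null(condition)) {
    ci <- match(condition, tfr@conditionNames)
    if (is.na(ci)) stop("unknown condition: ", condition)
    out <- out[ci, , ]
    dimnames(out) <- NULL
  }
  out
}
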