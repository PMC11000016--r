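# FIR band-pass filtering (Hamming windowed sinc), zero phase.

# Zero-phase band-pass of one vector. The kernel is a Hamming-windowed sinc
# (signal::fir1) whose order follows the transition-width rule
# N ~ 3.3 * fs / tw with tw = max(1 Hz, 25% of the lower band edge); because
# the kernel is symmetric, a single centred convolution is zero-phase. Short
# signals get the largest admissible (broader-transition) kernel.
firBandpass <- function(x, band, sfreq) {
  nyq <- sfreq / 2
  if (band[2] >= nyq) stop("upper band edge must be below Nyquist")
  if (band[1] <= 0) stop("lower band edge must be > 0")
  tw <- max(1, 0.25 * band[1])
  N <- ceiling(3.3 * sfreq / tw)
  N <- N + N %% 2                          # even order, odd-length kernel
  maxN <- 2 * floor((length(x) - 1) / 2)
  if (N > maxN) N <- maxN
  if (N < 8) stop("signal too short for band-pass filtering")
  kern <- signal::fir1(N, band / nyq, type = "pass")
  half <- N / 2
  # reflection padding keeps edge transients local
  xp <- c(rev(x[seq_len(half) + 1]), x,
          rev(x[(length(x) - half):(length(x) - 1)]))
  y <- stats::filter(xp, kern, method = "convolution", sides = 2)
  as.numeric(y[(half + 1):(half + length(x))])
}

#' Zero-phase FIR band-pass filtering of an EpochArray
#'
#' Applies a Hamming-windowed sinc FIR band-pass, channel by channel and trial
#' by trial. The symmetric kernel is applied as a single centred convolution,
#' so the output is zero-phase with the single-pass magnitude response
#' (filtering twice therefore squares the response - the usual LTI cascade
#' property). The kernel order follows a transition-width rule (about
#' 3.3 cycles of the transition width), capped by the epoch length.
#'
#' @param epochs an [EpochArray-class].
#' @param band band tag ("theta", "alpha", "beta") or length-2 Hz vector,
#'   strictly inside (0, Nyquist).
#' @return filtered [EpochArray-class] of identical shape.
#' @export
bandpassFIR <- function(epochs, band) {
  stopifnot(is(epochs, "EpochArray"))
  edges <- if (is.character(band)) {
    if (!band %in% names(FREQ_BANDS)) stop("unknown band tag: ", band)
    FREQ_BANDS[[band]]
  } else band
  dat <- epochData(epochs)
  d <- dim(dat)
  for (tr in seq_len(d[3])) for (ch in seq_len(d[1]))
    dat[ch, , tr] <- firBandpass(dat[ch, , tr], edges, samplingRate(epochs))
  initialize(epochs, data = dat)
}
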