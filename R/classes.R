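#' @import methods
#' @importFrom stats sd var rnorm runif quantile median qt pt dist coef
#'   lm optim convolve fft mvfft aggregate complete.cases setNames predict
#' @importFrom utils head tail read.delim write.table modifyList
NULL

#' EpochArray: epoched multichannel time series
#'
#' Container for stimulus-locked epochs: a `channels x time x trials` numeric
#' array plus the sampling rate, the time axis, per-trial condition labels and
#' (optionally) sensor positions used to build channel adjacency.
#'
#' The canonical epoch window runs from -2000 ms to +2000 ms around stimulus
#' onset at 256 Hz, inclusive at both endpoints (1025 samples); the onset
#' sample is the index at which time is 0.
#'
#' @slot data numeric array, channels x time x trials.
#' @slot times numeric vector of sample times in seconds (length = dim 2).
#' @slot sfreq sampling frequency in Hz.
#' @slot channelNames character vector (length = dim 1).
#' @slot channelPositions numeric matrix channels x 3 (may have 0 rows when
#'   sensor geometry is unknown).
#' @slot conditions character vector of per-trial condition labels
#'   (length = dim 3).
#' @slot onsetSample integer index of the stimulus-onset sample.
#' @export
setClass("EpochArray",
  representation(
    data = "array",
    times = "numeric",
    sfreq = "numeric",
    channelNames = "character",
    channelPositions = "matrix",
    conditions = "character",
    onsetSample = "integer"
  )
)

setValidity("EpochArray", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-d array (channels x time x trials)")
  else {
    if (length(object@times) != d[2])
      msg <- c(msg, "times length must equal dim(data)[2]")
    if (length(object@channelNames) != d[1])
      msg <- c(msg, "channelNames length must equal dim(data)[1]")
    if (length(object@conditions) != d[3])
      msg <- c(msg, "conditions length must equal dim(data)[3]")
    if (nrow(object@channelPositions) > 0 &&
        nrow(object@channelPositions) != d[1])
      msg <- c(msg, "channelPositions rows must equal dim(data)[1]")
    if (object@onsetSample < 1L || object@onsetSample > d[2])
      msg <- c(msg, "onsetSample out of range")
  }
  if (length(object@sfreq) != 1L || object@sfreq <= 0)
    msg <- c(msg, "sfreq must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochArray
#'
#' @param data channels x time x trials array.
#' @param sfreq sampling rate in Hz.
#' @param times time axis in seconds; defaults to an onset-centred axis.
#' @param channelNames,channelPositions,conditions,onsetSample see slots.
#' @return An [EpochArray-class] object.
#' @export
EpochArray <- function(data, sfreq, times = NULL, channelNames = NULL,
                       channelPositions = NULL, conditions = NULL,
                       onsetSample = NULL) {
  d <- dim(data)
  if (is.null(times)) {
    if (is.null(onsetSample)) onsetSample <- (d[2] + 1L) %/% 2L
    times <- (seq_len(d[2]) - onsetSample) / sfreq
  }
  if (is.null(onsetSample)) {
    onsetSample <- which.min(abs(times))
  }
  if (is.null(channelNames)) channelNames <- sprintf("ch%02d", seq_len(d[1]))
  if (is.null(channelPositions))
    channelPositions <- matrix(numeric(0), nrow = 0, ncol = 3)
  if (is.null(conditions)) conditions <- rep("all", d[3])
  new("EpochArray", data = data, times = as.numeric(times),
      sfreq = as.numeric(sfreq), channelNames = channelNames,
      channelPositions = channelPositions,
      conditions = as.character(conditions),
      onsetSample = as.integer(onsetSample))
}

setMethod("show", "EpochArray", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochArray: %d channels x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], object@sfreq))
  cat(sprintf("  window: %.3f .. %.3f s (onset sample %d)\n",
              min(object@times), max(object@times), object@onsetSample))
  tb <- table(object@conditions)
  cat("  conditions:", paste(sprintf("%s (%d)", names(tb), tb),
                             collapse = ", "), "\n")
})

#' Leadfield: forward model from voxels to sensors
#'
#' Gain matrix mapping unit source activity at each voxel of a regular grid to
#' sensor amplitudes, with the voxel and channel geometry used to build it.
#'
#' @slot gain numeric matrix, voxels x channels.
#' @slot voxelPositions numeric matrix, voxels x 3 (arbitrary units).
#' @slot channelPositions numeric matrix, channels x 3.
#' @slot channelNames character vector.
#' @export
setClass("Leadfield",
  representation(
    gain = "matrix",
    voxelPositions = "matrix",
    channelPositions = "matrix",
    channelNames = "character"
  )
)

setValidity("Leadfield", function(object) {
  msg <- character()
  if (nrow(object@voxelPositions) != nrow(object@gain))
    msg <- c(msg, "voxelPositions rows must equal gain rows")
  if (ncol(object@voxelPositions) != 3L)
    msg <- c(msg, "voxelPositions must have 3 columns")
  if (length(object@channelNames) != ncol(object@gain))
    msg <- c(msg, "channelNames length must equal gain columns")
  if (any(!is.finite(object@gain)))
    msg <- c(msg, "gain must be finite")
  if (any(rowSums(abs(object@gain)) == 0))
    msg <- c(msg, "gain has an all-zero voxel row")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Leadfield", function(object) {
  cat(sprintf("Leadfield: %d voxels x %d channels\n",
              nrow(object@gain), ncol(object@gain)))
})

#' TFR: time-frequency representation
#'
#' Morlet wavelet power, per condition, channel, frequency and time.
#' Edge samples where the wavelet overruns the epoch are NA. After decibel
#' baseline normalization (`dbNormalized = TRUE`) values are in dB relative to
#' the mean baseline power of each channel x frequency.
#'
#' @slot power numeric 4-d array: condition x channel x frequency x time.
#' @slot freqs analysis frequencies in Hz.
#' @slot times time axis in seconds.
#' @slot conditionNames condition labels (dim 1 of power).
#' @slot channelNames channel labels (dim 2 of power).
#' @slot baselineWindow numeric length-2; `c(NA, NA)` before normalization.
#' @slot dbNormalized logical flag.
#' @export
setClass("TFR",
  representation(
    power = "array",
    freqs = "numeric",
    times = "numeric",
    conditionNames = "character",
    channelNames = "character",
    baselineWindow = "numeric",
    dbNormalized = "logical"
  )
)

setValidity("TFR", function(object) {
  d <- dim(object@power)
  msg <- character()
  if (length(d) != 4L) msg <- c(msg, "power must be 4-d")
  else {
    if (length(object@conditionNames) != d[1])
      msg <- c(msg, "conditionNames length mismatch")
    if (length(object@channelNames) != d[2])
      msg <- c(msg, "channelNames length mismatch")
    if (length(object@freqs) != d[3]) msg <- c(msg, "freqs length mismatch")
    if (length(object@times) != d[4]) msg <- c(msg, "times length mismatch")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TFR", function(object) {
  d <- dim(object@power)
  cat(sprintf(
    "TFR: %d conditions x %d channels x %d freqs (%g..%g Hz) x %d samples%s\n",
    d[1], d[2], d[3], min(object@freqs), max(object@freqs), d[4],
    if (object@dbNormalized) " [dB-normalized]" else ""))
})

#' SpatialFilter: LCMV beamformer weights
#'
#' Common spatial filter computed from the regularized sensor covariance of
#' all relevant conditions; satisfies the unit-gain constraint
#' `W[v, ] %*% gain[v, ] == 1` for every voxel.
#'
#' @slot weights numeric matrix, voxels x channels.
#' @slot regularization fraction of mean sensor variance added to the diagonal.
#' @slot covarianceCondition condition number of the regularized covariance.
#' @export
setClass("SpatialFilter",
  representation(
    weights = "matrix",
    regularization = "numeric",
    covarianceCondition = "numeric"
  )
)

setMethod("show", "SpatialFilter", function(object) {
  cat(sprintf("SpatialFilter: %d voxels x %d channels (reg %.3g, cond %.3g)\n",
              nrow(object@weights), ncol(object@weights),
              object@regularization, object@covarianceCondition))
})

#' NMVARModel: nonlinear multivariate autoregressive model
#'
#' Order-p model of M node series in which each current sample is predicted
#' from the p past samples of all nodes through the sum of an explicit linear
#' map and a one-hidden-layer tanh network:
#' `x(n) = A %*% xp + W2 tanh(W1 xp + b1) + b2 + noise`.
#' With all hidden weights at zero the model is an ordinary VAR(p).
#'
#' @slot M node count.
#' @slot p model order (number of lags).
#' @slot A linear weights, array M x M x p; `A[j, i, k]` is the linear effect
#'   of node i at lag k on node j.
#' @slot W1,b1,W2,b2 hidden-layer parameters of the nonlinear part.
#' @slot J0 Jacobian of the raw hidden path at the origin (M x M*p). The
#'   model's linear/nonlinear split is made identifiable by absorbing this
#'   first-order term into `A`, so the nonlinear part has zero slope at the
#'   operating point and only carries structure a linear map cannot.
#' @slot center,scale per-node standardization applied before training.
#' @slot sigma estimated innovation SD per node (standardized scale).
#' @slot loss final training loss (mean squared one-step error).
#' @slot converged logical optimizer flag.
#' @slot seed integer training seed.
#' @export
setClass("NMVARModel",
  representation(
    M = "integer", p = "integer",
    A = "array",
    W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
    J0 = "matrix",
    center = "numeric", scale = "numeric",
    sigma = "numeric", loss = "numeric", converged = "logical",
    seed = "integer"
  )
)

setValidity("NMVARModel", function(object) {
  msg <- character()
  dA <- dim(object@A)
  if (length(dA) != 3L || dA[1] != object@M || dA[2] != object@M ||
      dA[3] != object@p)
    msg <- c(msg, "A must be M x M x p")
  if (ncol(object@W1) != object@M * object@p)
    msg <- c(msg, "W1 must have M*p columns")
  if (nrow(object@W2) != object@M)
    msg <- c(msg, "W2 must have M rows")
  if (ncol(object@W2) != nrow(object@W1))
    msg <- c(msg, "W2 cols must equal hidden size")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NMVARModel", function(object) {
  cat(sprintf(
    "NMVARModel: M=%d nodes, order p=%d, %d hidden units (loss %.4g%s)\n",
    object@M, object@p, nrow(object@W1), object@loss,
    if (object@converged) "" else ", NOT converged"))
})

#' ConnectivityMatrix: directed linear and nonlinear connectivity
#'
#' M x M matrices of linear (`lC`) and nonlinear (`NC`) directed connectivity,
#' entry `[i, j]` quantifying the influence of node i on node j. The diagonal
#' (self-connections) is reported but excluded from non-self averages and from
#' the normalization reference.
#'
#' @slot lC,NC numeric M x M matrices, nonnegative.
#' @slot normalized TRUE after division by the subject-level maximum non-self
#'   value across bands and conditions (per measure).
#' @slot band frequency band tag ("theta", "alpha", "beta" or "").
#' @slot process gating process tag ("opening", "closing" or "").
#' @slot nodeNames node labels.
#' @export
setClass("ConnectivityMatrix",
  representation(
    lC = "matrix", NC = "matrix",
    normalized = "logical",
    band = "character", process = "character",
    nodeNames = "character"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  if (!all(dim(object@lC) == dim(object@NC)))
    msg <- c(msg, "lC and NC must have identical dimensions")
  if (nrow(object@lC) != ncol(object@lC))
    msg <- c(msg, "connectivity matrices must be square")
  if (any(object@lC < 0, na.rm = TRUE) || any(object@NC < 0, na.rm = TRUE))
    msg <- c(msg, "connectivity values must be nonnegative")
  if (object@normalized) {
    off <- row(object@lC) != col(object@lC)
    if (any(object@lC[off] > 1 + 1e-12) || any(object@NC[off] > 1 + 1e-12))
      msg <- c(msg, "normalized non-self values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @param lC,NC M x M nonnegative matrices (influence of row node on column
#'   node).
#' @param band,process,nodeNames,normalized see slots.
#' @rdname ConnectivityMatrix-class
#' @export
ConnectivityMatrix <- function(lC, NC, band = "", process = "",
                               nodeNames = NULL, normalized = FALSE) {
  if (is.null(nodeNames)) nodeNames <- sprintf("node%d", seq_len(nrow(lC)))
  new("ConnectivityMatrix", lC = lC, NC = NC, normalized = normalized,
      band = band, process = process, nodeNames = nodeNames)
}

setMethod("show", "ConnectivityMatrix", function(object) {
  off <- row(object@lC) != col(object@lC)
  cat(sprintf(
    "ConnectivityMatrix: %d nodes%s%s%s | mean non-self lC %.3g, NC %.3g\n",
    nrow(object@lC),
    if (nzchar(object@band)) paste0(", band=", object@band) else "",
    if (nzchar(object@process)) paste0(", process=", object@process) else "",
    if (object@normalized) " [normalized]" else "",
    mean(object@lC[off]), mean(object@NC[off])))
})
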