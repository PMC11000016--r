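#' LCMV common spatial filter
#'
#' Linearly constrained minimum-variance beamformer with a fixed-orientation
#' scalar leadfield: `W(v) = (g' C^-1 g)^-1 g' C^-1` with `C` the regularized
#' sensor covariance of all relevant conditions appended. The unit-gain
#' constraint `W(v) . g(v) = 1` holds algebraically for every voxel. By
#' default `C` is the average of single-trial covariances; `covMode =
#' "average"` instead uses the covariance of the trial-averaged data.
#'
#' @param epochs an [EpochArray-class] holding the appended conditions.
#' @param leadfield a [Leadfield-class] on the analysis grid.
#' @param reg diagonal loading as a fraction of the mean sensor variance.
#' @param covMode `"trials"` (default) or `"average"`.
#' @return a [SpatialFilter-class].
#' @export
lcmvCommonFilter <- function(epochs, leadfield, reg = 0.05,
                             covMode = c("trials", "average")) {
  stopifnot(is(epochs, "EpochArray"), is(leadfield, "Leadfield"))
  covMode <- match.arg(covMode)
  dat <- epochData(epochs)
  d <- dim(dat)
  if (d[1] != ncol(gainMatrix(leadfield)))
    stop("channel count of epochs and leadfield differ")
  C <- matrix(0, d[1], d[1])
  if (covMode == "trials") {
    for (tr in seq_len(d[3])) C <- C + stats::cov(t(dat[, , tr]))
    C <- C / d[3]
  } else {
    C <- stats::cov(t(apply(dat, c(1, 2), mean)))
  }
  lam <- reg * mean(diag(C))
  Creg <- C + lam * diag(d[1])
  if (reg <= 0 && rcond(Creg) < 1e-12)
    stop("sensor covariance is rank-deficient; increase regularization")
  Cinv <- solve(Creg)
  G <- gainMatrix(leadfield)               # voxels x channels
  GC <- G %*% Cinv                         # voxels x channels
  denom <- rowSums(GC * G)                 # g' C^-1 g per voxel
  W <- GC / denom
  new("SpatialFilter", weights = W, regularization = reg,
      covarianceCondition = kappa(Creg, exact = FALSE))
}

#' Reconstruct source time series with a spatial filter
#'
#' @param filter a [SpatialFilter-class].
#' @param epochs an [EpochArray-class] with matching channels.
#' @return array voxels x time x trials.
#' @export
reconstructSources <- function(filter, epochs) {
  stopifnot(is(filter, "SpatialFilter"), is(epochs, "EpochArray"))
  dat <- epochData(epochs)
  d <- dim(dat)
  W <- filterWeights(filter)
  if (ncol(W) != d[1]) stop("channel count mismatch")
  out <- array(0, dim = c(nrow(W), d[2], d[3]))
  for (tr in seq_len(d[3])) out[, , tr] <- W %*% dat[, , tr]
  out
}

#' Per-voxel gating contrast of source activity
#'
#' Switch minus nonswitch source activity per voxel. 3-d inputs
#' (voxels x time x trials) or 2-d inputs (voxels x trials) are reduced to
#' per-voxel mean power (mean square); 1-d inputs are taken as per-voxel
#' activity values directly, in which case the contrast is linear in its
#' inputs.
#'
#' @param switchSrc,nonswitchSrc source arrays/vectors on the same voxel grid.
#' @return numeric per-voxel effect vector.
#' @export
sourceGatingContrast <- function(switchSrc, nonswitchSrc) {
  red <- function(x) {
    if (is.null(dim(x))) return(as.numeric(x))
    apply(x, 1, function(v) mean(v^2))
  }
  a <- red(switchSrc); b <- red(nonswitchSrc)
  if (length(a) != length(b)) stop("voxel grids do not match")
  a - b
}

#' Select the top percentile of voxels by absolute effect
#'
#' Keeps `ceiling(pct/100 * n)` voxels with the largest |effect|; absolute
#' value is used so suppression effects (alpha/beta power decreases) are
#' selectable. Ties are broken by voxel index (lower index first).
#'
#' @param effect per-voxel effect map.
#' @param pct percentage of voxels to keep (default 1).
#' @return integer voxel indices, in decreasing |effect| order.
#' @export
selectTopVoxels <- function(effect, pct = 1) {
  n <- length(effect)
  if (!n) stop("empty effect map")
  nSel <- ceiling(pct / 100 * n)
  ord <- order(-abs(effect), seq_len(n))
  ord[seq_len(nSel)]
}

#' DBSCAN clustering of selected voxel positions
#'
#' Standard density-based clustering: a point with at least `minPts` points
#' (itself included) within radius `eps` is a core point; clusters are the
#' connected sets reachable from core points, and non-reachable points are
#' noise and discarded. With the default `minPts = 2`, a cluster needs at
#' least 2 voxels and isolated voxels are dropped. The result does not depend
#' on the input ordering.
#'
#' @param positions points x 3 coordinate matrix (e.g. selected voxels).
#' @param eps neighborhood radius; a regular grid connects face/edge
#'   neighbors at `eps = 1.5 *` grid spacing.
#' @param minPts minimum points to form a cluster.
#' @return list with `assignment` (integer per point; 0 = noise) and
#'   `clusters`, a data.frame with `cluster_id`, `n_voxels` and centroid
#'   coordinates `cx, cy, cz`.
#' @export
dbscanCluster <- function(positions, eps, minPts = 2) {
  stopifnot(eps > 0, minPts >= 1)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  D <- as.matrix(dist(positions))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))  # self included
  core <- vapply(nb, length, integer(1)) >= minPts
  assignment <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (assignment[i] != 0L || !core[i]) next
    cid <- cid + 1L
    assignment[i] <- cid
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (assignment[j] == 0L) {
        assignment[j] <- cid
        if (core[j]) queue <- c(queue, nb[[j]][assignment[nb[[j]]] == 0L])
      }
    }
  }
  ids <- seq_len(cid)
  clusters <- do.call(rbind, lapply(ids, function(k) {
    pts <- positions[assignment == k, , drop = FALSE]
    data.frame(cluster_id = k, n_voxels = nrow(pts),
               cx = mean(pts[, 1]), cy = mean(pts[, 2]), cz = mean(pts[, 3]))
  }))
  if (is.null(clusters))
    clusters <- data.frame(cluster_id = integer(0), n_voxels = integer(0),
                           cx = numeric(0), cy = numeric(0), cz = numeric(0))
  list(assignment = assignment, clusters = clusters)
}

#' Extract baseline-subtracted cluster-averaged source signals
#'
#' For every switch trial and voxel, the mean nonswitch source signal of that
#' voxel is subtracted; the residuals are then averaged over the voxels of
#' each cluster and cropped to the connectivity window (default -500..1500 ms,
#' half-open `[t0, t1)`, i.e. 512 samples at 256 Hz).
#'
#' @param voxelTs switch-trial source array, voxels x time x trials.
#' @param clusterVoxels list of integer voxel-index vectors, one per cluster.
#' @param nonswitchMean voxels x time matrix of mean nonswitch source signal.
#' @param times time axis in seconds (length = dim 2 of `voxelTs`).
#' @param window length-2 crop window in seconds.
#' @return list per cluster: `data` (cropped samples x trials),
#'   `times` (cropped axis), `voxels`.
#' @export
extractClusterSignals <- function(voxelTs, clusterVoxels, nonswitchMean,
                                  times, window = c(-0.5, 1.5)) {
  d <- dim(voxelTs)
  stopifnot(length(times) == d[2],
            all(dim(nonswitchMean) == d[1:2]))
  sel <- times >= window[1] & times < window[2]
  if (!any(sel)) stop("crop window outside the epoch")
  lapply(clusterVoxels, function(vox) {
    if (any(vox < 1 | vox > d[1]))
      stop("cluster references a voxel outside the source array")
    sig <- matrix(0, sum(sel), d[3])
    for (tr in seq_len(d[3])) {
      resid <- matrix(voxelTs[vox, , tr], nrow = length(vox)) -
        nonswitchMean[vox, , drop = FALSE]
      sig[, tr] <- colMeans(resid)[sel]
    }
    list(data = sig, times = times[sel], voxels = vox)
  })
}
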