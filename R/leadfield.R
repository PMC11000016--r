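#' Synthetic leadfield on a regular voxel grid
#'
#' Builds a smooth, distance-decaying gain matrix for testing source
#' reconstruction: voxels on a regular 3-d grid (unit spacing), channels on a
#' surrounding Fibonacci sphere with a small seeded jitter, and
#' `gain[v, c] = exp(-d(v, c)^2 / (2 * lambda^2))`. Because the gain decays
#' monotonically with distance, each voxel's maximal-gain channel is its
#' nearest channel. Deterministic given `seed`.
#'
#' @param nVoxels number of voxels; factored into the most cubic grid
#'   `nx x ny x nz` with `nx*ny*nz == nVoxels` (>= 2).
#' @param nChannels number of channels (>= 2).
#' @param seed integer seed (jitters channel positions only).
#' @return a [Leadfield-class].
#' @export
makeLeadfield <- function(nVoxels, nChannels, seed = 1) {
  stopifnot(nVoxels >= 2, nChannels >= 2)
  dims <- cubicDims(nVoxels)
  vox <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                               z = seq_len(dims[3])))
  vox <- vox * 1.0
  centre <- colMeans(vox)
  halfDiag <- sqrt(sum(((dims - 1) / 2)^2))
  R <- 1.4 * max(halfDiag, 1) + 1
  # Fibonacci sphere: near-uniform channel layout
  i <- seq_len(nChannels) - 0.5
  phi <- acos(1 - 2 * i / nChannels)
  theta <- pi * (1 + sqrt(5)) * i
  ch <- cbind(R * sin(phi) * cos(theta),
              R * sin(phi) * sin(theta),
              R * cos(phi))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, 505L))
  ch <- ch + matrix(rnorm(3 * nChannels, sd = 0.02), ncol = 3)
  ch <- sweep(ch, 2, centre, `+`)
  d2 <- outer(rowSums(vox^2), rowSums(ch^2), `+`) - 2 * vox %*% t(ch)
  d2[d2 < 0] <- 0
  lambda <- 0.45 * R
  gain <- exp(-d2 / (2 * lambda^2))
  new("Leadfield", gain = gain, voxelPositions = unname(vox),
      channelPositions = unname(ch),
      channelNames = sprintf("ch%03d", seq_len(nChannels)))
}

# most cubic integer factorization nx <= ny <= nz with product n
cubicDims <- function(n) {
  best <- c(1, 1, n)
  bestSpread <- n
  for (a in seq_len(n)) {
    if (a^3 > n) break
    if (n %% a != 0) next
    m <- n / a
    for (b in a:m) {
      if (b^2 > m) break
      if (m %% b != 0) next
      cc <- m / b
      if (cc - a < bestSpread) {
        bestSpread <- cc - a
        best <- c(a, b, cc)
      }
    }
  }
  as.integer(best)
}
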