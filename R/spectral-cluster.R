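#' Channel adjacency from sensor positions
#'
#' Two channels are neighbors when their distance is at most `mult` times the
#' median nearest-neighbor distance - a geometry-free rule suited to the
#' synthetic sensor layouts used here.
#'
#' @param positions channels x 3 position matrix.
#' @param mult distance multiplier (default 1.5).
#' @return logical channels x channels adjacency matrix (FALSE diagonal).
#' @export
channelAdjacency <- function(positions, mult = 1.5) {
  stopifnot(is.matrix(positions), nrow(positions) >= 2)
  D <- as.matrix(dist(positions))
  diag(D) <- Inf
  thr <- mult * median(apply(D, 1, min))
  adj <- D <= thr
  diag(adj) <- FALSE
  adj
}

#' Cluster-based permutation test for paired condition differences
#'
#' Nonparametric family-wise corrected test over a channel x time grid.
#' A within-subject paired t is computed at every point; points with two-sided
#' p <= `clusterAlpha` are clustered with their suprathreshold neighbors
#' (adjacent time samples on the same channel, adjacent channels at the same
#' sample) separately by sign, and each cluster's statistic is its summed t.
#' The null distribution is the maximum absolute cluster sum under random
#' within-subject sign flips (the exchangeability scheme for paired designs),
#' and each observed cluster gets the two-sided Monte-Carlo p-value
#' `(1 + #(null >= |sum t|)) / (nPerm + 1)`, which is bounded below by
#' `1/(nPerm + 1)`.
#'
#' @param condA,condB numeric arrays subjects x channels x time (same shape).
#' @param adjacency logical channels x channels neighbor matrix
#'   (see [channelAdjacency()]).
#' @param nPerm number of Monte-Carlo draws.
#' @param alpha significance level for reporting clusters.
#' @param clusterAlpha cluster-forming threshold (two-sided pointwise alpha).
#' @param seed integer RNG seed.
#' @return list (ClusterResult) with `clusters` (each: `points` matrix with
#'   columns channel/time, `stat`, `polarity`, `p`, `significant`), `tmap`,
#'   `threshold`, `nPerm`. With no suprathreshold point, `clusters` is empty
#'   and `p` is reported as 1.
#' @export
clusterPermTest <- function(condA, condB, adjacency, nPerm = 1000,
                            alpha = 0.05, clusterAlpha = 0.05, seed = 1) {
  stopifnot(all(dim(condA) == dim(condB)))
  d <- dim(condA)
  nSub <- d[1]
  if (nSub < 6) stop("need >= 6 subjects for the permutation test")
  stopifnot(nrow(adjacency) == d[2])
  nC <- d[2]; nT <- d[3]
  D <- condA - condB
  Dm <- matrix(D, nrow = nSub)              # subjects x (channel*time)
  ss <- colSums(Dm^2)
  thr <- qt(1 - clusterAlpha / 2, nSub - 1)
  adjList <- apply(adjacency, 1, which, simplify = FALSE)

  tFromSigns <- function(signs) {
    m <- colSums(Dm * signs) / nSub
    v <- (ss - nSub * m^2) / (nSub - 1)
    tv <- m / sqrt(v / nSub)
    tv[v <= 0] <- 0
    tv
  }

  tObs <- tFromSigns(rep(1, nSub))
  obsClusters <- findTClusters(tObs, thr, nC, nT, adjList)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(childSeed(seed, 606L))
  nullMax <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    signs <- sample(c(-1, 1), nSub, replace = TRUE)
    tv <- tFromSigns(signs)
    nullMax[b] <- maxAbsClusterSum(tv, thr, nC, nT, adjList)
  }

  clusters <- lapply(obsClusters, function(cl) {
    pval <- (1 + sum(nullMax >= abs(cl$stat))) / (nPerm + 1)
    pts <- cbind(channel = ((cl$idx - 1) %% nC) + 1,
                 time = ((cl$idx - 1) %/% nC) + 1)
    list(points = pts, stat = cl$stat,
         polarity = sign(cl$stat), p = pval,
         significant = pval <= alpha)
  })
  list(clusters = clusters,
       tmap = matrix(tObs, nC, nT),
       threshold = thr,
       nPerm = nPerm,
       p = if (length(clusters)) min(vapply(clusters, `[[`, numeric(1), "p"))
           else 1)
}

# connected components of suprathreshold points sharing a sign; points are
# indexed channel-fastest in a channel x time grid
findTClusters <- function(tv, thr, nC, nT, adjList) {
  supra <- which(abs(tv) > thr & is.finite(tv))
  if (!length(supra)) return(list())
  inSet <- logical(nC * nT)
  inSet[supra] <- TRUE
  visited <- logical(nC * nT)
  sgn <- sign(tv)
  out <- list()
  for (p0 in supra) {
    if (visited[p0]) next
    stack <- p0
    visited[p0] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      pt <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, pt)
      ch <- ((pt - 1) %% nC) + 1
      ti <- ((pt - 1) %/% nC) + 1
      nb <- integer(0)
      if (ti > 1) nb <- c(nb, pt - nC)
      if (ti < nT) nb <- c(nb, pt + nC)
      nbCh <- adjList[[ch]]
      if (length(nbCh)) nb <- c(nb, (ti - 1) * nC + nbCh)
      nb <- nb[inSet[nb] & !visited[nb] & sgn[nb] == sgn[pt]]
      if (length(nb)) {
        visited[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
    out[[length(out) + 1]] <- list(idx = sort(members),
                                   stat = sum(tv[members]))
  }
  out[order(-vapply(out, function(cl) abs(cl$stat), numeric(1)))]
}

maxAbsClusterSum <- function(tv, thr, nC, nT, adjList) {
  cl <- findTClusters(tv, thr, nC, nT, adjList)
  if (!length(cl)) 0 else abs(cl[[1]]$stat)
}
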