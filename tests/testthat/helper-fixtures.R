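# shared fixtures and small utilities for the test suite

# rank-based AUC of scores against binary labels
rankAUC <- function(scores, labels) {
  r <- rank(scores)
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# stationary 5-node linear VAR(2) with a few directed edges
linearVARSpec <- function(noiseSd = 1) {
  M <- 5
  A1 <- matrix(0, M, M); diag(A1) <- 0.4
  A1[2, 1] <- 0.5; A1[4, 3] <- -0.4; A1[5, 2] <- 0.35
  A2 <- matrix(0, M, M); diag(A2) <- -0.3; A2[3, 1] <- 0.3
  couplingSpec(M, 2, list(A1, A2), noiseSd = noiseSd)
}

# 2-node system whose only cross-coupling is a square term 1 -> 2
squareCouplingSpec <- function(gain = 0.6) {
  couplingSpec(2, 1, list(diag(c(0.5, 0.5))),
               nonlinearTerms = list(list(source = 1, target = 2, lag = 1,
                                          fun = "square", gain = gain)),
               noiseSd = 1)
}

# tiny trial table with known structure
toyTrials <- function(nPerCell = 10, rt = 0.5) {
  cells <- expand.grid(switching = c("switch", "nonswitch"),
                       trial_type = c("reference", "comparison"),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(subject = "sub001", trial = seq_len(nPerCell),
               trial_type = cells$trial_type[i],
               switching = cells$switching[i],
               matching = "match", response = "match",
               correct = 1L, rt_s = rt, stringsAsFactors = FALSE)
  }))
}
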