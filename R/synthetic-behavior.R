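#' Cohort specification for synthetic reference-back behavior
#'
#' Defines the study conditions for the synthetic behavioral generator: the
#' four Switching x Trial Type cells of the reference-back task, each with
#' its own drift-diffusion parameters. The defaults reproduce the condition
#' structure of the reference-back study the pipeline targets: boundary
#' separation larger in switch (0.93) than nonswitch (0.86) trials with a
#' larger switch cost when closing the gate (0.09) than opening it (0.04);
#' non-decision time longer in switch (356 ms) than nonswitch (332 ms) trials
#' (closing cost 35 ms vs opening cost 11 ms); drift rate larger in switch
#' (0.09) than nonswitch (0.01) trials.
#'
#' @param nSubjects number of subjects.
#' @param trialsPerCondition trials per Switching x Trial Type cell (>= 1).
#' @param ddmParamsByCondition named list over
#'   `c("switch-reference", "nonswitch-reference", "switch-comparison",
#'   "nonswitch-comparison")` of [ddmParams()] objects.
#' @param pMatch probability that a trial's ground truth is "match",
#'   in (0, 1).
#' @param pReference probability that a trial is framed as a reference trial
#'   (the task's reference/comparison ratio is a free design parameter).
#' @param seed master seed; all per-subject/per-condition substreams derive
#'   from it.
#' @return list of class `"CohortSpec"`.
#' @export
cohortSpec <- function(nSubjects = 20,
                       trialsPerCondition = 80,
                       ddmParamsByCondition = NULL,
                       pMatch = 0.5,
                       pReference = 0.5,
                       seed = 1) {
  if (is.null(ddmParamsByCondition)) {
    ddmParamsByCondition <- list(
      "switch-reference"      = ddmParams(a = 0.950, v = 0.13, t0 = 0.3495),
      "nonswitch-reference"   = ddmParams(a = 0.910, v = 0.01, t0 = 0.3385),
      "switch-comparison"     = ddmParams(a = 0.905, v = 0.05, t0 = 0.3615),
      "nonswitch-comparison"  = ddmParams(a = 0.815, v = 0.01, t0 = 0.3265)
    )
  }
  if (!setequal(names(ddmParamsByCondition), GATING_CONDITIONS))
    stop("ddmParamsByCondition must be named by the four ",
         "Switching x Trial Type conditions")
  for (p in ddmParamsByCondition) {
    if (!inherits(p, "DDMParams")) stop("condition parameters must be ddmParams()")
  }
  if (trialsPerCondition < 1) stop("trialsPerCondition must be >= 1")
  if (pMatch <= 0 || pMatch >= 1) stop("pMatch must be in (0, 1)")
  if (pReference <= 0 || pReference >= 1)
    stop("pReference must be in (0, 1)")
  structure(list(nSubjects = as.integer(nSubjects),
                 trialsPerCondition = as.integer(trialsPerCondition),
                 ddmParamsByCondition = ddmParamsByCondition[GATING_CONDITIONS],
                 pMatch = pMatch, pReference = pReference,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Generate a synthetic reference-back trial table
#'
#' For each subject, frame colors (reference vs comparison) are drawn i.i.d.
#' with `pReference`; a trial is a "switch" when its trial type differs from
#' the previous trial's, and the first trial of the sequence, having no
#' predecessor, is unlabeled and dropped. The sequence is extended until every
#' Switching x Trial Type cell holds `trialsPerCondition` trials, and exactly
#' the first `trialsPerCondition` trials of each cell are kept, so the table
#' has `nSubjects * 4 * trialsPerCondition` rows. Ground-truth matching is
#' Bernoulli(`pMatch`); the response and RT of every trial are drawn from the
#' DDM simulator with the cell's parameters (upper boundary = "match"
#' response), and `correct` records whether the response equals the matching
#' ground truth. All RTs exceed the cell's t0 by construction.
#'
#' @param spec a [cohortSpec()].
#' @param dt Euler step for the simulator (seconds).
#' @return data.frame (TrialSet) with columns `subject, trial, trial_type,
#'   switching, matching, response, correct, rt_s`.
#' @export
genBehavior <- function(spec, dt = 1e-3) {
  stopifnot(inherits(spec, "CohortSpec"))
  tpc <- spec$trialsPerCondition
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  out <- vector("list", spec$nSubjects)
  for (s in seq_len(spec$nSubjects)) {
    set.seed(childSeed(spec$seed, 101L, s))
    # draw a frame-color sequence long enough to fill all four cells
    seqTypes <- character(0)
    counts <- setNames(integer(4), GATING_CONDITIONS)
    labels <- character(0)
    while (any(counts < tpc)) {
      block <- ifelse(runif(8 * tpc + 16) < spec$pReference,
                      "reference", "comparison")
      seqTypes <- c(seqTypes, block)
      sw <- c(NA, ifelse(seqTypes[-1] != seqTypes[-length(seqTypes)],
                         "switch", "nonswitch"))
      labels <- ifelse(is.na(sw), NA, conditionLabel(sw, seqTypes))
      counts <- vapply(GATING_CONDITIONS,
                       function(cc) sum(labels == cc, na.rm = TRUE),
                       integer(1))
    }
    # keep first tpc trials of each cell, in sequence order
    keep <- unlist(lapply(GATING_CONDITIONS, function(cc)
      head(which(!is.na(labels) & labels == cc), tpc)))
    keep <- sort(keep)
    cond <- labels[keep]
    matching <- ifelse(runif(length(keep)) < spec$pMatch,
                       "match", "mismatch")
    # simulate choices/RTs per cell, then place back in sequence order
    response <- character(length(keep))
    rt <- numeric(length(keep))
    for (ci in seq_along(GATING_CONDITIONS)) {
      cc <- GATING_CONDITIONS[ci]
      idx <- which(cond == cc)
      sim <- simulateDDM(spec$ddmParamsByCondition[[cc]], length(idx),
                         dt = dt, seed = childSeed(spec$seed, 202L, s, ci))
      response[idx] <- sim$boundary
      rt[idx] <- sim$rt_s
    }
    sw <- sub("-.*$", "", cond)
    tt <- sub("^.*-", "", cond)
    out[[s]] <- data.frame(
      subject = sprintf("sub%03d", s),
      trial = seq_along(keep),
      trial_type = tt,
      switching = sw,
      matching = matching,
      response = response,
      correct = as.integer(response == matching),
      rt_s = rt,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
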