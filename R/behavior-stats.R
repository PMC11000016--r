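#' Trial- and subject-level RT outlier filtering
#'
#' Removes, within each subject, trials whose RT lies outside the subject's
#' mean +/- k * SD (a subject with identical RTs has SD 0 and loses nothing;
#' `k = Inf` is the identity). Trial-level trimming is applied first; subject
#' exclusion flags are then computed on the trimmed data: a subject is flagged
#' when their mean RT, or any per-condition trial count, falls outside the
#' group mean +/- k * SD. Flags are returned in the `"subjectFlags"`
#' attribute; set `dropFlagged = TRUE` to also remove flagged subjects.
#'
#' @param trials trial table with columns `subject`, `rt_s` (and `switching`,
#'   `trial_type` for the count rule).
#' @param k SD multiplier (default 2).
#' @param dropFlagged remove flagged subjects from the returned table.
#' @return filtered trial table; attribute `"subjectFlags"` is a data.frame
#'   with `subject`, `mean_rt_flag`, `count_flag`, `excluded`.
#' @export
filterOutliers <- function(trials, k = 2, dropFlagged = FALSE) {
  stopifnot_cols(trials, c("subject", "rt_s"), "trials")
  subs <- unique(trials$subject)
  for (s in subs) {
    if (sum(trials$subject == s) < 3)
      stop("each subject needs >= 3 trials for outlier filtering")
  }
  keep <- rep(TRUE, nrow(trials))
  if (is.finite(k)) {
    for (s in subs) {
      idx <- which(trials$subject == s)
      m <- mean(trials$rt_s[idx])
      sdev <- sd(trials$rt_s[idx])
      if (sdev > 0)
        keep[idx] <- abs(trials$rt_s[idx] - m) <= k * sdev
    }
  }
  out <- trials[keep, , drop = FALSE]

  meanRT <- vapply(subs, function(s) mean(out$rt_s[out$subject == s]),
                   numeric(1))
  rtFlag <- flagOutsideGroup(meanRT, k)
  countFlag <- rep(FALSE, length(subs))
  if (all(c("switching", "trial_type") %in% names(out))) {
    condOf <- conditionLabel(out$switching, out$trial_type)
    for (cc in unique(condOf)) {
      cnt <- vapply(subs, function(s)
        sum(out$subject == s & condOf == cc), numeric(1))
      countFlag <- countFlag | flagOutsideGroup(cnt, k)
    }
  }
  emptyFlag <- vapply(subs, function(s) !any(out$subject == s), logical(1))
  flags <- data.frame(subject = subs,
                      mean_rt_flag = rtFlag | emptyFlag,
                      count_flag = countFlag,
                      excluded = rtFlag | countFlag | emptyFlag,
                      stringsAsFactors = FALSE)
  if (dropFlagged)
    out <- out[!out$subject %in% flags$subject[flags$excluded], ,
               drop = FALSE]
  attr(out, "subjectFlags") <- flags
  out
}

flagOutsideGroup <- function(x, k) {
  if (!is.finite(k) || length(x) < 2) return(rep(FALSE, length(x)))
  m <- mean(x); sdev <- sd(x)
  if (sdev == 0) return(rep(FALSE, length(x)))
  abs(x - m) > k * sdev
}

#' Per-subject condition summaries: mean RT (correct trials) and error rate
#'
#' @param trials trial table with `subject`, `switching`, `trial_type`,
#'   `correct`, `rt_s`.
#' @return data.frame with one row per subject x condition: `mean_rt_s`
#'   (mean over correct trials; NA when a cell has no correct trial) and
#'   `error_pct` (100 * errors / valid trials), plus trial count `n`.
#' @export
summarizeConditions <- function(trials) {
  stopifnot_cols(trials, c("subject", "switching", "trial_type", "correct",
                           "rt_s"), "trials")
  cells <- expand.grid(subject = unique(trials$subject),
                       switching = c("switch", "nonswitch"),
                       trial_type = c("reference", "comparison"),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    d <- trials[trials$subject == cells$subject[i] &
                  trials$switching == cells$switching[i] &
                  trials$trial_type == cells$trial_type[i], , drop = FALSE]
    corr <- d[d$correct == 1, , drop = FALSE]
    data.frame(cells[i, , drop = FALSE],
               condition = conditionLabel(cells$switching[i],
                                          cells$trial_type[i]),
               mean_rt_s = if (nrow(corr)) mean(corr$rt_s) else NA_real_,
               error_pct = if (nrow(d)) 100 * mean(d$correct == 0)
                           else NA_real_,
               n = nrow(d),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Gate opening / closing contrasts from the four condition cells
#'
#' Gate opening is the switch cost within reference trials, gate closing the
#' switch cost within comparison trials:
#' `opening = cell(switch, reference) - cell(nonswitch, reference)` and
#' `closing = cell(switch, comparison) - cell(nonswitch, comparison)`.
#' Applies to any per-cell measure (RT, error percentage, or a fitted DDM
#' parameter). The contrast is linear in its inputs.
#'
#' @param cells named numeric with entries `"switch-reference"`,
#'   `"nonswitch-reference"`, `"switch-comparison"`,
#'   `"nonswitch-comparison"`.
#' @param measure optional tag describing what the cells hold.
#' @return list (GatingScore) with `measure`, `opening`, `closing`.
#' @export
gatingContrast <- function(cells, measure = "") {
  missing <- setdiff(GATING_CONDITIONS, names(cells))
  if (length(missing))
    stop("missing condition cell(s): ", paste(missing, collapse = ", "))
  if (any(is.na(cells[GATING_CONDITIONS])))
    stop("condition cells contain NA")
  list(measure = measure,
       opening = unname(cells["switch-reference"] -
                          cells["nonswitch-reference"]),
       closing = unname(cells["switch-comparison"] -
                          cells["nonswitch-comparison"]))
}

#' Repeated-measures ANOVA for fully within-subject 2-level designs
#'
#' For 2- or 3-factor designs with two levels per factor, every main effect
#' and interaction has one numerator degree of freedom, so its F statistic is
#' exactly the squared one-sample t of the per-subject contrast scores. Cell
#' columns must follow `expand.grid` order of the factor levels (first factor
#' varying fastest, level 1 before level 2). Subjects with missing cells are
#' dropped (with a message).
#'
#' @param cellMatrix numeric matrix, subjects x 2^k cells.
#' @param factors character vector of k factor names (k in 2:3).
#' @return data.frame with one row per effect: `effect`, `F`, `df_num`,
#'   `df_err`, `p`, `eta_p2`.
#' @export
rmAnova <- function(cellMatrix, factors) {
  k <- length(factors)
  if (!k %in% 2:3) stop("factors must name 2 or 3 two-level factors")
  cellMatrix <- as.matrix(cellMatrix)
  if (ncol(cellMatrix) != 2^k)
    stop(sprintf("cellMatrix must have %d columns for %d factors", 2^k, k))
  complete <- complete.cases(cellMatrix)
  if (any(!complete)) {
    message(sum(!complete), " subject(s) dropped for missing cells")
    cellMatrix <- cellMatrix[complete, , drop = FALSE]
  }
  n <- nrow(cellMatrix)
  if (n < 2) stop("need >= 2 complete subjects")
  # +1/-1 codes per factor in expand.grid order
  codes <- as.matrix(expand.grid(rep(list(c(1, -1)), k)))
  colnames(codes) <- factors
  effects <- unlist(lapply(seq_len(k), function(m)
    combn(factors, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(effects, function(eff) {
    w <- apply(codes[, eff, drop = FALSE], 1, prod) / 2^(k - 1)
    score <- drop(cellMatrix %*% w)
    m <- mean(score); se <- sd(score) / sqrt(n)
    tval <- if (se == 0) 0 else m / se
    Fval <- tval^2
    dfe <- n - 1
    data.frame(effect = paste(eff, collapse = " x "),
               F = Fval, df_num = 1, df_err = dfe,
               p = stats::pf(Fval, 1, dfe, lower.tail = FALSE),
               eta_p2 = etaSquaredFromF(Fval, 1, dfe),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired-sample t test with the paired effect size d_z
#'
#' Classical paired t; the effect size convention is `d_z = t / sqrt(n)`
#' (equivalently, mean difference over SD of differences), the convention
#' consistent with repeated-measures reporting of (t, d) pairs. Zero-variance
#' differences give the documented degenerate result: t = 0 (p = 1) when all
#' differences are zero, t = +/-Inf (p = 0) otherwise.
#'
#' @param x,y paired numeric vectors of equal length n >= 2.
#' @return list with `t`, `df`, `p`, `d`.
#' @export
pairedT <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  sdev <- sd(d)
  if (sdev == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 1, d = 0))
    tv <- sign(mean(d)) * Inf
    return(list(t = tv, df = n - 1, p = 0, d = tv))
  }
  tv <- mean(d) / (sdev / sqrt(n))
  list(t = tv, df = n - 1,
       p = 2 * pt(abs(tv), n - 1, lower.tail = FALSE),
       d = tv / sqrt(n))
}

#' Partial eta squared from an F statistic
#'
#' `eta_p2 = F * df_num / (F * df_num + df_err)`; strictly increasing in F
#' for fixed dfs and bounded in [0, 1).
#'
#' @param F F statistic (>= 0).
#' @param dfNum,dfErr numerator / error degrees of freedom.
#' @return partial eta squared.
#' @export
etaSquaredFromF <- function(F, dfNum = 1, dfErr) {
  if (any(F < 0)) stop("F must be nonnegative")
  stopifnot(dfErr >= 1)
  F * dfNum / (F * dfNum + dfErr)
}

#' Paired Cohen's d_z from a t statistic
#'
#' `d_z = t / sqrt(n)` with n the number of pairs.
#'
#' @param t paired t statistic.
#' @param n number of pairs (>= 1).
#' @return Cohen's d_z.
#' @export
cohensDzFromT <- function(t, n) {
  stopifnot(n >= 1)
  t / sqrt(n)
}
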