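#' Maximum-likelihood DDM fit for one condition cell
#'
#' Fits (a, v, t0) by maximizing the summed log Wiener first-passage density
#' with response-coded boundaries: "match" responses contribute the
#' upper-boundary density, "mismatch" responses the lower-boundary density.
#' `zr` is fixed at 0.5 and inter-trial variabilities at 0 (see
#' [ddmParams()]). Derivative-free simplex optimization with seeded
#' multi-starts; deterministic given `seed`.
#'
#' @param rt response times in seconds.
#' @param response character, "match"/"upper" or "mismatch"/"lower" per trial.
#' @param precision series accuracy passed to [wfptDensity()].
#' @param nRestarts number of seeded simplex restarts (best likelihood kept).
#' @param seed integer seed for the restart jitter.
#' @param minTrials fitting floor; fewer trials raise an error.
#' @return list with `a`, `v`, `t0`, `loglik`, `n`, `converged`.
#' @export
fitDDMCell <- function(rt, response, precision = 4, nRestarts = 5, seed = 1,
                       minTrials = 20) {
  stopifnot(length(rt) == length(response))
  keep <- is.finite(rt) & rt > 0
  rt <- rt[keep]
  response <- as.character(response)[keep]
  response <- gsub("^upper$", "match", gsub("^lower$", "mismatch", response))
  if (!all(response %in% c("match", "mismatch")))
    stop("response must be 'match'/'mismatch' (or 'upper'/'lower')")
  n <- length(rt)
  if (n < minTrials)
    stop(sprintf("only %d trials; fitting floor is %d", n, minTrials))
  rtU <- rt[response == "match"]
  rtL <- rt[response == "mismatch"]
  minRT <- min(rt)

  negll <- function(theta) {
    aa <- exp(theta[1])
    if (aa < 0.3 || aa > 3) return(1e10)
    vv <- theta[2]
    if (abs(vv) > 5) return(1e10)
    tt0 <- minRT * stats::plogis(theta[3])
    dU <- if (length(rtU))
      wfptDensity(rtU, aa, vv, tt0, boundary = "upper",
                  precision = precision) else numeric(0)
    dL <- if (length(rtL))
      wfptDensity(rtL, aa, vv, tt0, boundary = "lower",
                  precision = precision) else numeric(0)
    ll <- sum(log(pmax(dU, 1e-300))) + sum(log(pmax(dL, 1e-300)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # moment-based initialization: for zr = 0.5, P(match) = plogis(v * a)
  pU <- max(0.02, min(0.98, length(rtU) / n))
  t0i <- 0.85 * minRT
  mdt <- max(mean(rt) - t0i, 1e-3)
  ai <- min(2.5, max(0.35, 2 * sqrt(mdt)))
  vi <- stats::qlogis(pU) / ai
  start0 <- c(log(ai), vi, stats::qlogis(0.85))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    start <- if (r == 1) start0 else
      start0 + rnorm(3, sd = c(0.25, 0.5, 0.75))
    fit <- tryCatch(
      optim(start, negll, method = "Nelder-Mead",
            control = list(maxit = 800, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    return(list(a = NA_real_, v = NA_real_, t0 = NA_real_,
                loglik = NA_real_, n = n, converged = FALSE))
  list(a = exp(best$par[1]),
       v = best$par[2],
       t0 = minRT * stats::plogis(best$par[3]),
       loglik = -best$value,
       n = n,
       converged = best$convergence == 0)
}

#' Fit the DDM per subject and Switching x Trial Type condition
#'
#' Only correct trials enter the fit, with boundaries coded by the response
#' ("match" = upper, "mismatch" = lower), mirroring the behavioral-modeling
#' conventions of the reference-back task.
#'
#' @param trials a trial table (see [genBehavior()]) with columns `subject`,
#'   `switching`, `trial_type`, `response`, `correct`, `rt_s`.
#' @param correctOnly keep only correct trials (default TRUE).
#' @inheritParams fitDDMCell
#' @return data.frame with one row per subject x condition:
#'   `subject, switching, trial_type, condition, a, v, t0, loglik, n,
#'   converged`. Cells below the trial floor or failing to converge are
#'   reported with NA parameters.
#' @export
fitDDM <- function(trials, correctOnly = TRUE, precision = 4, nRestarts = 5,
                   seed = 1, minTrials = 20) {
  stopifnot_cols(trials, c("subject", "switching", "trial_type",
                           "response", "correct", "rt_s"), "trials")
  if (correctOnly) trials <- trials[trials$correct == 1, , drop = FALSE]
  cells <- unique(trials[, c("subject", "switching", "trial_type")])
  cells <- cells[order(cells$subject, cells$switching, cells$trial_type), ,
                 drop = FALSE]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- cells$subject[i]; sw <- cells$switching[i]
    tt <- cells$trial_type[i]
    d <- trials[trials$subject == sub & trials$switching == sw &
                  trials$trial_type == tt, , drop = FALSE]
    fit <- tryCatch(
      fitDDMCell(d$rt_s, d$response, precision = precision,
                 nRestarts = nRestarts,
                 seed = childSeed(seed, match(sub, unique(cells$subject)),
                                  (sw == "switch") + 2L *
                                    (tt == "reference")),
                 minTrials = minTrials),
      error = function(e) list(a = NA_real_, v = NA_real_, t0 = NA_real_,
                               loglik = NA_real_, n = nrow(d),
                               converged = FALSE))
    data.frame(subject = sub, switching = sw, trial_type = tt,
               condition = conditionLabel(sw, tt),
               a = fit$a, v = fit$v, t0 = fit$t0, loglik = fit$loglik,
               n = fit$n, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
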