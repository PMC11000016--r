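#' Drift-diffusion model parameters
#'
#' Parameter container following the conventions used for modeling the
#' reference-back task: the diffusion coefficient is fixed at 1 so the
#' boundary separation is on the usual 0.8-1.0 scale, the relative start
#' point `zr` is fixed at 0.5, and the inter-trial variabilities and the
#' contaminant proportion are fixed at 0.
#'
#' @param a boundary separation (> 0), decision threshold/caution.
#' @param v drift rate (evidence accumulation speed; positive drifts toward
#'   the upper = "match" boundary).
#' @param t0 non-decision time in seconds (encoding + motor; >= 0).
#' @param zr relative start point, fixed at 0.5 in this design.
#' @return a named list of class `"DDMParams"`.
#' @export
ddmParams <- function(a, v, t0, zr = 0.5) {
  if (!is.finite(a) || a <= 0) stop("boundary separation a must be > 0")
  if (!is.finite(t0) || t0 < 0) stop("non-decision time t0 must be >= 0")
  if (!is.finite(v)) stop("drift rate v must be finite")
  if (zr <= 0 || zr >= 1) stop("relative start zr must be in (0, 1)")
  structure(list(a = a, v = v, t0 = t0, zr = zr,
                 szr = 0, sv = 0, p_contaminant = 0),
            class = "DDMParams")
}

#' Simulate two-choice trials from the drift-diffusion model
#'
#' Euler-Maruyama walk starting at `zr * a`, drift `v`, unit diffusion,
#' absorbed at 0 (lower = "mismatch") or `a` (upper = "match");
#' `rt = first-passage time + t0`. Trials not absorbed within `maxT` seconds
#' are resampled (the count is returned as an attribute).
#'
#' @param params a [ddmParams()] object.
#' @param n number of trials.
#' @param dt Euler step in seconds; steps of 1e-4 (default) keep the
#'   discretization bias on fitted parameters well below recovery tolerances.
#' @param seed integer RNG seed.
#' @param maxT non-absorption cap in seconds.
#' @return data.frame with columns `boundary` ("match"/"mismatch") and
#'   `rt_s`; attribute `"resampled"` counts trials that hit the cap.
#' @export
simulateDDM <- function(params, n, dt = 1e-4, seed = 1, maxT = 10) {
  stopifnot(inherits(params, "DDMParams"), n >= 1, dt > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  a <- params$a; v <- params$v; t0 <- params$t0; zr <- params$zr
  sdt <- sqrt(dt)
  maxSteps <- ceiling(maxT / dt)
  rt <- numeric(n)
  upper <- logical(n)
  resampled <- 0L
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    x <- rep(zr * a, m)
    steps <- integer(m)
    active <- seq_len(m)
    res_rt <- numeric(m)
    res_up <- logical(m)
    done <- logical(m)
    for (s in seq_len(maxSteps)) {
      x[active] <- x[active] + v * dt + sdt * rnorm(length(active))
      hit <- x[active] <= 0 | x[active] >= a
      if (any(hit)) {
        idx <- active[hit]
        res_rt[idx] <- s * dt
        res_up[idx] <- x[idx] >= a
        done[idx] <- TRUE
        active <- active[!hit]
      }
      if (!length(active)) break
    }
    finished <- which(done)
    rt[todo[finished]] <- res_rt[finished] + t0
    upper[todo[finished]] <- res_up[finished]
    notdone <- which(!done)
    resampled <- resampled + length(notdone)
    if (length(notdone) >= m)
      stop("DDM simulation failed to absorb any trial within maxT; ",
           "check parameters")
    todo <- todo[notdone]
  }
  out <- data.frame(
    boundary = ifelse(upper, "match", "mismatch"),
    rt_s = rt,
    stringsAsFactors = FALSE
  )
  attr(out, "resampled") <- resampled
  out
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
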