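#' Wiener first-passage time density
#'
#' Density of the first-passage time of a Wiener diffusion (unit diffusion
#' coefficient) with drift `v`, boundary separation `a`, relative start point
#' `zr` and non-decision time `t0`, at the lower ("mismatch") or upper
#' ("match") boundary. Uses the standard small-time/large-time series
#' expansions with the truncation for each evaluation point chosen from an
#' error-bound comparison, so the absolute error of the standardized density
#' is below `10^-precision` (default precision 4, i.e. error <= 1e-4).
#'
#' @param t evaluation times in seconds (vectorized). Density is 0 for
#'   `t <= t0`.
#' @param a boundary separation (> 0).
#' @param v drift rate.
#' @param t0 non-decision time in seconds (>= 0).
#' @param zr relative start point in (0, 1); 0.5 = unbiased.
#' @param boundary `"lower"`/`"mismatch"` or `"upper"`/`"match"`.
#' @param precision decimal digits of absolute accuracy of the series.
#' @return numeric vector of densities.
#' @seealso [boundaryProb()] for the probability of absorption at each
#'   boundary, [simulateDDM()] for sampling.
#' @export
wfptDensity <- function(t, a, v, t0, zr = 0.5,
                        boundary = c("lower", "upper"), precision = 4) {
  boundary <- match.arg(gsub("^match$", "upper",
                             gsub("^mismatch$", "lower", boundary[1])),
                        c("lower", "upper"))
  stopifnot(a > 0, zr > 0, zr < 1, t0 >= 0)
  if (boundary == "upper") {
    v <- -v
    zr <- 1 - zr
  }
  out <- numeric(length(t))
  ok <- which(t > t0 & is.finite(t))
  if (!length(ok)) return(out)
  tt <- t[ok] - t0
  tau <- tt / a^2                      # standardized time
  eps <- 10^(-precision)
  fn <- vapply(tau, wfptStdDensity, numeric(1), w = zr, eps = eps)
  out[ok] <- fn * exp(-v * a * zr - v^2 * tt / 2) / a^2
  out
}

# standardized lower-boundary density f(tau | 0, 1, w), scalar tau
wfptStdDensity <- function(tau, w, eps) {
  if (tau <= 0) return(0)
  # number of terms needed by each expansion (error bound <= eps)
  ks <- if (2 * eps * sqrt(2 * pi * tau) < 1) {
    max(2 + sqrt(-2 * tau * log(2 * eps * sqrt(2 * pi * tau))),
        sqrt(tau) + 1)
  } else 2
  kl <- if (pi * tau * eps < 1) {
    max(sqrt(-2 * log(pi * tau * eps) / (pi^2 * tau)),
        1 / (pi * sqrt(tau)))
  } else 1 / (pi * sqrt(tau))
  if (ks < kl) {
    K <- ceiling(ks)
    k <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    sum((w + 2 * k) * exp(-((w + 2 * k)^2) / (2 * tau))) /
      sqrt(2 * pi * tau^3)
  } else {
    K <- ceiling(kl)
    k <- seq_len(K)
    pi * sum(k * exp(-k^2 * pi^2 * tau / 2) * sin(k * pi * w))
  }
}

#' Boundary absorption probabilities of the Wiener diffusion
#'
#' Closed-form probability that the diffusion with drift `v`, boundary
#' separation `a` and relative start `zr` is absorbed at the requested
#' boundary: `P(upper) = (exp(-2 v a zr) - 1) / (exp(-2 v a) - 1)` for
#' `v != 0` and `zr` for `v = 0`.
#'
#' @inheritParams wfptDensity
#' @return absorption probability.
#' @export
boundaryProb <- function(a, v, zr = 0.5, boundary = c("upper", "lower")) {
  boundary <- match.arg(gsub("^match$", "upper",
                             gsub("^mismatch$", "lower", boundary[1])),
                        c("upper", "lower"))
  stopifnot(a > 0, zr > 0, zr < 1)
  pUpper <- if (abs(v) < 1e-12) {
    zr
  } else {
    expm1(-2 * v * a * zr) / expm1(-2 * v * a)
  }
  if (boundary == "upper") pUpper else 1 - pUpper
}
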