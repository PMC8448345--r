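#' Parameters of the simplified symmetry-breaking-time model
#'
#' The simplified model places an overdamped object on a locally
#' quadratic potential bump, `V(r) = -k r^2 / 2`, so a small initial
#' offset `r0` grows exponentially, `r(t) = r0 exp(t/tau)` with
#' relaxation timescale `tau = damping / k_bump`. The symmetry-breaking
#' time is the first passage at a set distance `r_c`; when `r0` is
#' Gaussian the breaking times follow a right-skewed closed-form
#' density.
#'
#' Defaults (`sigma0 = 1`, `tau = 1`, `r_c = 10`) are the values used
#' for the reference density plots.
#'
#' @param tau relaxation timescale.
#' @param sigma0 SD of the Gaussian initial offset.
#' @param r_c symmetry-breaking distance.
#' @param k_bump bump curvature (optional; implies `tau = damping/k_bump`
#'   when both are given).
#' @param damping damping coefficient (optional).
#' @return named list of class `analyticParams`.
#' @export
analyticParams <- function(tau = 1, sigma0 = 1, r_c = 10,
                           k_bump = NULL, damping = NULL) {
  if (!is.null(k_bump) && !is.null(damping)) tau <- damping / k_bump
  stopifnot(tau > 0, sigma0 > 0, r_c > 0)
  p <- list(tau = tau, sigma0 = sigma0, r_c = r_c,
            k_bump = k_bump, damping = damping)
  class(p) <- c("analyticParams", "list")
  p
}

#' Symmetry-breaking time for a given initial offset
#'
#' First-passage time of the exponential escape `r(t) = r0 exp(t/tau)`
#' at the breaking distance `r_c`: `t_c = tau * log(r_c / |r0|)`.
#' Negative when `|r0| > r_c` (the breaking distance was passed before
#' t = 0). An offset of exactly zero sits on the unstable equilibrium
#' and never escapes: `Inf` is returned with a warning.
#'
#' @param r0 initial offset(s); the absolute value is used.
#' @param p an [analyticParams()] list.
#' @return breaking time(s), same length as `r0`.
#' @examples
#' breakingTime(1, analyticParams()) # log(10)
#' @export
breakingTime <- function(r0, p = analyticParams()) {
  out <- p$tau * log(p$r_c / abs(r0))
  if (any(r0 == 0)) {
    warning("r0 = 0 lies on the unstable equilibrium; breaking time is Inf")
    out[r0 == 0] <- Inf
  }
  out
}

#' Closed-form density of the symmetry-breaking time
#'
#' For a Gaussian initial offset of SD `sigma0`, the breaking time
#' `t_c = tau log(r_c/|r0|)` has density
#' `p(t) = (2 r_c / (sigma0 tau sqrt(2 pi))) exp(-t/tau)
#'   exp(-(r_c exp(-t/tau)/sigma0)^2 / 2)`,
#' supported on the whole line, unimodal with mode at
#' `tau log(r_c/sigma0)` and skewed to the right — the long tail is a
#' direct consequence of the nonlinear (logarithmic) dependence of the
#' breaking time on the initial offset.
#'
#' @param t time(s).
#' @param p an [analyticParams()] list.
#' @return density value(s).
#' @export
breakingTimePdf <- function(t, p = analyticParams()) {
  z <- p$r_c * exp(-t / p$tau) / p$sigma0
  2 * p$r_c / (p$sigma0 * p$tau * sqrt(2 * pi)) *
    exp(-t / p$tau) * exp(-z^2 / 2)
}

#' Closed-form CDF of the symmetry-breaking time
#'
#' `P(t_c <= t) = P(|r0| >= r_c exp(-t/tau)) =
#'   2 (1 - Phi(r_c exp(-t/tau) / sigma0))` (folded-normal tail).
#'
#' @inheritParams breakingTimePdf
#' @return cumulative probability value(s).
#' @export
breakingTimeCdf <- function(t, p = analyticParams()) {
  2 * stats::pnorm(p$r_c * exp(-t / p$tau) / p$sigma0, lower.tail = FALSE)
}

#' Monte-Carlo sampler of symmetry-breaking times
#'
#' Draws Gaussian initial offsets and maps them through
#' [breakingTime()]; exact draws from the closed-form density, used to
#' cross-check it. Offsets of exactly zero (probability zero) are
#' redrawn.
#'
#' @param n number of draws.
#' @param p an [analyticParams()] list.
#' @param seed optional RNG seed.
#' @return numeric vector of `n` breaking times.
#' @export
sampleBreakingTimes <- function(n, p = analyticParams(), seed = NA) {
  if (!is.na(seed)) set.seed(seed)
  r0 <- stats::rnorm(n, 0, p$sigma0)
  while (any(r0 == 0)) r0[r0 == 0] <- stats::rnorm(sum(r0 == 0), 0, p$sigma0)
  breakingTime(r0, p)
}

#' Euler integration of the escape from a quadratic bump
#'
#' Integrates `dr/dt = r / tau` with explicit Euler steps and reports
#' the trajectory and the first-passage time at `r_c` (linear
#' interpolation between the bracketing steps). The closed-form
#' solution is `r(t) = r0 exp(t/tau)`.
#'
#' @param r0 initial offset.
#' @param p an [analyticParams()] list.
#' @param dt Euler step.
#' @param t_end integration horizon; default runs a little past the
#'   expected passage time.
#' @return list with `t`, `r` (trajectory vectors) and `t_passage`
#'   (NA if `r_c` was not reached; Inf if `r0 = 0`).
#' @export
simulateBump <- function(r0, p = analyticParams(), dt = 1e-3,
                         t_end = NULL) {
  stopifnot(dt > 0)
  if (is.null(t_end)) {
    t_end <- if (r0 == 0) 5 * p$tau else
      max(2 * dt, 1.2 * abs(p$tau * log(p$r_c / abs(r0))) + p$tau)
  }
  nt <- ceiling(t_end / dt)
  r <- numeric(nt + 1)
  r[1] <- r0
  for (i in seq_len(nt)) r[i + 1] <- r[i] + r[i] / p$tau * dt
  tt <- (0:nt) * dt
  tp <- NA_real_
  if (r0 == 0) tp <- Inf else {
    hit <- which(abs(r) >= p$r_c)
    if (length(hit)) {
      j <- hit[1]
      if (j == 1) tp <- 0 else {
        f <- (p$r_c - abs(r[j - 1])) / (abs(r[j]) - abs(r[j - 1]))
        tp <- tt[j - 1] + f * dt
      }
    }
  }
  list(t = tt, r = r, t_passage = tp)
}
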