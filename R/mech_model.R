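#' Parameters of the two-cluster spindle mechanics model
#'
#' Bundles and validates the parameters of the overdamped model of
#' anaphase II spindle rotation: two DNA clusters attracted to fixed
#' cortical zones through a soft-core potential, connected by a spindle
#' of fixed length that resists bending, while the central-spindle
#' point is pushed inward at constant speed by the cytokinetic furrow.
#' Distances are in units of the oocyte radius `R_ovo` (fixed at 1) and
#' time is arbitrary (the damping coefficient sets the scale).
#'
#' Defaults are the parameter set used throughout the study:
#' `A = 1.5e2`, `lam = 1e-1`, `r_a = (4/3)e-1`, `k = 2e2`,
#' `damping = 1`, `u_cyto = 1/3`.
#'
#' @param A attraction amplitude (well depth scale).
#' @param lam decay length of the attraction potential (units of R_ovo).
#' @param r_a radius of the potential well, roughly the DNA cluster
#'   radius; the potential is minimal at `r = r_a`.
#' @param k spindle bending stiffness (force per unit deflection).
#' @param damping damping coefficient; velocities are force/damping.
#' @param u_cyto constant ingression speed of the central spindle.
#' @param sigma SD of the Gaussian positional noise added to each
#'   cluster coordinate at every time step (units of R_ovo). Note the
#'   noise is a per-step displacement, not scaled by sqrt(dt), so the
#'   effective diffusion depends on `dt`; `dt` is therefore part of the
#'   parameter set.
#' @param dt Euler time step.
#' @param t_max maximum simulated time.
#' @param R_ovo oocyte radius (fixed 1).
#' @param L0 initial inter-cluster chord length (units of R_ovo).
#' @param alpha_stop rotation angle (degrees) below which a run is
#'   considered complete.
#' @param r_escape cluster-to-anchor distance beyond which the run is
#'   terminated (default `r_a + 5*lam`).
#' @param sym_tol tolerance on max |r1 - r2| below which a run is
#'   classified symmetric.
#' @param seed integer RNG seed recorded with the run (optional; the
#'   `seed` argument of [simulateSpindle()] takes precedence).
#'
#' @return a named list of class `modelParams`.
#' @examples
#' p <- modelParams(sigma = 1e-3)
#' p$A
#' @export
modelParams <- function(A = 1.5e2, lam = 1e-1, r_a = (4 / 3) * 1e-1,
                        k = 2e2, damping = 1, u_cyto = 1 / 3,
                        sigma = 0, dt = 1e-3, t_max = 3, R_ovo = 1,
                        L0 = 0.8, alpha_stop = 5,
                        r_escape = r_a + 5 * lam, sym_tol = 1e-8,
                        seed = NA_integer_) {
  stopifnot(lam > 0, r_a > 0, dt > 0, t_max > 0, u_cyto >= 0,
            sigma >= 0, R_ovo > 0, L0 > 0, L0 < 2 * R_ovo,
            damping > 0, alpha_stop >= 0, r_escape > 0, sym_tol > 0)
  p <- list(A = A, lam = lam, r_a = r_a, k = k, damping = damping,
            u_cyto = u_cyto, sigma = sigma, dt = dt, t_max = t_max,
            R_ovo = R_ovo, L0 = L0, alpha_stop = alpha_stop,
            r_escape = r_escape, sym_tol = sym_tol,
            seed = as.integer(seed))
  class(p) <- c("modelParams", "list")
  p
}

#' Soft-core cortical attraction potential
#'
#' `V(r) = -A (r - r_a + lam) exp(-r/lam)`: a short-range repulsive,
#' mid-range attractive effective potential with a unique minimum at
#' `r = r_a` (cluster apposed to the attraction zone) that decays to 0
#' at large distance.
#'
#' @param r distance(s) to the cortical attraction zone, `>= 0`.
#' @param params a [modelParams()] list.
#' @return potential value(s), same length as `r`.
#' @examples
#' p <- modelParams()
#' potentialV(p$r_a, p) # well depth, about -3.954
#' @export
potentialV <- function(r, params = modelParams()) {
  if (any(r < 0)) stop("distance r must be non-negative")
  -params$A * (r - params$r_a + params$lam) * exp(-r / params$lam)
}

#' Attraction force of a cortical zone on a DNA cluster
#'
#' Gradient force of [potentialV()]: directed toward the anchor for
#' `r > r_a`, away from it for `r < r_a`, zero at the well minimum.
#' Magnitude `(A/lam) |r - r_a| exp(-r/lam)`.
#'
#' @param pos 2D cluster position.
#' @param anchor 2D fixed cortical anchor point.
#' @param params a [modelParams()] list.
#' @return 2D force vector. A cluster exactly on its anchor (r = 0) is
#'   degenerate and yields a zero force with a warning.
#' @export
attractionForce <- function(pos, anchor, params = modelParams()) {
  d <- pos - anchor
  r <- sqrt(sum(d^2))
  if (r == 0) {
    warning("cluster coincides with its anchor; force set to zero")
    return(c(0, 0))
  }
  # dV/dr = -A exp(-r/lam) (r_a - r) / lam ; force = -dV/dr * u_r
  dV <- -params$A * exp(-r / params$lam) * (params$r_a - r) / params$lam
  -dV * d / r
}

#' Elastic restoring force from spindle bending
#'
#' The spindle deflection `w` is the component of (central-spindle
#' point minus cluster-chord midpoint) perpendicular to the chord; the
#' restoring force `k * w` acts identically on both clusters, pulling
#' them after the ingressing central spindle.
#'
#' @param state a spindle state as returned by [initState()].
#' @param params a [modelParams()] list.
#' @return list with `force` (2D vector) and `w` (2D deflection vector).
#' @export
elasticForce <- function(state, params = modelParams()) {
  ch <- state$x2 - state$x1
  n <- sqrt(sum(ch^2))
  if (n == 0) stop("coincident clusters: chord direction undefined")
  u <- ch / n
  mid <- (state$x1 + state$x2) / 2
  w <- state$c - mid
  w <- w - sum(w * u) * u
  list(force = params$k * w, w = w)
}

#' Initial spindle configuration
#'
#' Places the two clusters symmetrically about the vertical polarity
#' axis on the circle of radius `R_ovo - r_a` with chord length `L0`,
#' so each cluster starts exactly in its potential well. Anchors are
#' the radial projections of the clusters onto the cortex; the
#' central-spindle point starts at the chord midpoint; the ingression
#' direction is the inward chord normal.
#'
#' @param params a [modelParams()] list.
#' @return a list with elements `x1`, `x2`, `c`, `a1`, `a2` (2D
#'   points), `dir` (unit ingression direction) and `t` (time, 0).
#' @export
initState <- function(params = modelParams()) {
  R <- params$R_ovo
  rc <- R - params$r_a
  h <- params$L0 / 2
  if (params$L0 >= 2 * rc)
    stop("L0 too large: clusters cannot sit in their wells (L0 >= 2*(R_ovo - r_a))")
  y <- sqrt(rc^2 - h^2)
  x1 <- c(-h, y); x2 <- c(h, y)
  a1 <- x1 / sqrt(sum(x1^2)) * R
  a2 <- x2 / sqrt(sum(x2^2)) * R
  list(x1 = x1, x2 = x2, c = c(0, y), a1 = a1, a2 = a2,
       dir = c(0, -1), t = 0)
}

.state_to_core <- function(state, params, tmax, thin, early_stop) {
  sim_core(state$x1, state$x2, state$c, state$a1, state$a2, state$dir,
           state$t, params$A, params$lam, params$r_a, params$k,
           params$damping, params$u_cyto, params$sigma, params$dt,
           tmax, params$R_ovo, sqrt(sum((state$x2 - state$x1)^2)),
           params$alpha_stop, params$r_escape, as.integer(thin),
           early_stop)
}

#' Advance the spindle state by one Euler step
#'
#' One explicit Euler step of the overdamped dynamics
#' `v = (f_V + f_E)/damping`, followed by the per-step Gaussian noise
#' kick, exact re-projection of the pair to the fixed chord length,
#' containment inside the oocyte disc, the prescribed advance of the
#' central-spindle point and the continuity update of the ingression
#' direction. Uses the current R RNG stream for the noise.
#'
#' @param state a state list as from [initState()].
#' @param params a [modelParams()] list.
#' @return the updated state list.
#' @export
stepState <- function(state, params = modelParams()) {
  res <- .state_to_core(state, params, tmax = state$t + params$dt,
                        thin = 1L, early_stop = FALSE)
  list(x1 = res$x1, x2 = res$x2, c = res$c, a1 = state$a1,
       a2 = state$a2, dir = res$dir, t = res$t)
}

.rotation_angle_xy <- function(ix, iy, mx, my) {
  # angle at the spindle midpoint between the internalized cluster and
  # the oocyte centroid (origin), degrees
  v1x <- ix - mx; v1y <- iy - my
  n1 <- sqrt(v1x^2 + v1y^2)
  n2 <- sqrt(mx^2 + my^2)
  cosb <- (-v1x * mx - v1y * my) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosb))) * 180 / pi
}

#' Simulate one run of the spindle rotation model
#'
#' Runs the Euler loop from the symmetric initial configuration until
#' `t_max`, rotation completion (rotation angle below
#' `params$alpha_stop` degrees) or escape of a cluster beyond
#' `params$r_escape`. In/out labels are assigned retrospectively: the
#' "out" (extruded) cluster is the one with the smaller final cortex
#' distance, the "in" cluster internalizes. A run is "symmetric" when
#' max |r1 - r2| stayed below `params$sym_tol` for its whole duration.
#' Seeded runs are bitwise reproducible.
#'
#' @param params a [modelParams()] list.
#' @param seed integer RNG seed; `NA` leaves the RNG stream untouched.
#' @param thin record every `thin`-th Euler step (the first and last
#'   step are always recorded).
#' @param early_stop logical; apply the termination thresholds (TRUE)
#'   or always run to `t_max`.
#' @return a [Trajectory-class] object.
#' @examples
#' tr <- simulateSpindle(modelParams(sigma = 1e-3, t_max = 1), seed = 1)
#' trajOutcome(tr)
#' @export
simulateSpindle <- function(params = modelParams(), seed = params$seed,
                            thin = 10L, early_stop = TRUE) {
  if (!is.na(seed)) set.seed(seed)
  st <- initState(params)
  res <- .state_to_core(st, params, tmax = params$t_max, thin = thin,
                        early_stop = early_stop)
  fr <- as.data.frame(res$frames)
  names(fr) <- c("t", "x1x", "x1y", "x2x", "x2y", "cx", "cy")
  fr$r1 <- sqrt((fr$x1x - st$a1[1])^2 + (fr$x1y - st$a1[2])^2)
  fr$r2 <- sqrt((fr$x2x - st$a2[1])^2 + (fr$x2y - st$a2[2])^2)
  fr$d1 <- params$R_ovo - sqrt(fr$x1x^2 + fr$x1y^2)
  fr$d2 <- params$R_ovo - sqrt(fr$x2x^2 + fr$x2y^2)
  fr$depth <- params$u_cyto * fr$t

  n <- nrow(fr)
  symmetric <- res$max_dr < params$sym_tol
  in_idx <- if (symmetric) NA_integer_ else
    if (fr$d1[n] >= fr$d2[n]) 1L else 2L
  mx <- (fr$x1x + fr$x2x) / 2
  my <- (fr$x1y + fr$x2y) / 2
  lab <- if (is.na(in_idx)) 1L else in_idx # symmetric: either, equal
  fr$alpha <- if (lab == 1L) .rotation_angle_xy(fr$x1x, fr$x1y, mx, my)
              else .rotation_angle_xy(fr$x2x, fr$x2y, mx, my)

  new("Trajectory", params = unclass(params), frames = fr,
      anchors = rbind(st$a1, st$a2),
      outcome = if (symmetric) "symmetric" else "broken",
      inIndex = in_idx, maxAsym = res$max_dr,
      stopReason = c("tmax", "rotation_complete", "escape")[res$reason + 1],
      seed = as.integer(seed))
}

#' Run a seeded ensemble of spindle simulations
#'
#' Runs `n` independent simulations from deterministic sub-seeds of
#' `seed` and tabulates per-run symmetry-breaking statistics: rotation
#' onset time `ti` (five-parameter logistic fit of the rotation curve,
#' with an empirical 5%-of-span fallback flagged in `ti_method`), the
#' early-window in/out cortex-distance ratio, the outcome side and the
#' final rotation angle.
#'
#' @param params a [modelParams()] list.
#' @param n number of runs.
#' @param seed base seed for the ensemble.
#' @param early_fraction fraction of `t_max` defining the early
#'   analysis window for the in/out ratio (model time is arbitrary;
#'   the default first 10% plays the role of the first minutes of a
#'   recording).
#' @param fit_onset compute `ti` (TRUE) or skip the logistic fits for
#'   speed (FALSE, `ti` column all NA).
#' @param thin recording stride passed to [simulateSpindle()].
#' @return data.frame with one row per run: `seed`, `outcome`,
#'   `in_index`, `ti`, `ti_method`, `inout_ratio`, `final_alpha`,
#'   `max_asym`, `stop_reason`.
#' @examples
#' es <- runEnsemble(modelParams(sigma = 1e-2), n = 5, seed = 1)
#' mean(es$inout_ratio > 1)
#' @export
runEnsemble <- function(params = modelParams(), n = 1000L, seed = 1L,
                        early_fraction = 1 / 6, fit_onset = TRUE,
                        thin = 10L) {
  stopifnot(n >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- simulateSpindle(params, seed = seeds[i], thin = thin)
    m <- trajMetrics(tr, early_fraction = early_fraction,
                     fit_onset = fit_onset)
    rows[[i]] <- data.frame(seed = seeds[i], outcome = tr@outcome,
                            in_index = tr@inIndex, ti = m$ti,
                            ti_method = m$ti_method,
                            inout_ratio = m$inout_ratio,
                            final_alpha = m$final_alpha,
                            max_asym = tr@maxAsym,
                            stop_reason = tr@stopReason)
  }
  do.call(rbind, rows)
}
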