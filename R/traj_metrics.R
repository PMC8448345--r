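#' Inter-cluster distance series
#'
#' Euclidean distance between the two DNA clusters per frame: 3D in
#' physical micrometres for an imaging-derived [ClusterTrack-class],
#' 2D in units of the oocyte radius for a simulated
#' [Trajectory-class]. Frames where only one cluster was detected
#' yield NA.
#'
#' @param track a `ClusterTrack` or `Trajectory`.
#' @return data.frame with columns `t` and `d`.
#' @export
clusterDistance <- function(track) {
  if (is(track, "Trajectory")) {
    fr <- track@frames
    return(data.frame(t = fr$t,
                      d = sqrt((fr$x2x - fr$x1x)^2 + (fr$x2y - fr$x1y)^2)))
  }
  fr <- trackFrames(track)
  data.frame(t = fr$t,
             d = sqrt((fr$c2x - fr$c1x)^2 + (fr$c2y - fr$c1y)^2 +
                        (fr$c2z - fr$c1z)^2))
}

#' Register recordings on the anaphase onset
#'
#' Fits a least-squares line through the early, linearly increasing
#' phase of the inter-cluster distance and defines the intercept of
#' that line with the time axis as t = 0. When no window is given, the
#' initial strictly increasing run of `d` is used.
#'
#' @param t time vector.
#' @param d inter-cluster distance vector.
#' @param window optional length-2 time window for the linear fit.
#' @return the time offset `t0` (subtract it from `t` to register);
#'   errors if fewer than 3 points fall in the window or the fitted
#'   slope is not positive (no anaphase separation detected).
#' @export
registerTime <- function(t, d, window = NULL) {
  ok <- is.finite(t) & is.finite(d)
  t <- t[ok]; d <- d[ok]
  if (is.null(window)) {
    inc <- which(diff(d) <= 0)
    last <- if (length(inc)) inc[1] else length(t) - 1
    idx <- seq_len(last + 1)
  } else {
    idx <- which(t >= window[1] & t <= window[2])
  }
  if (length(idx) < 3)
    stop("registration window must contain at least 3 points")
  fit <- stats::lm.fit(cbind(1, t[idx]), d[idx])
  b <- fit$coefficients
  if (!is.finite(b[2]) || b[2] <= 0)
    stop("non-positive slope in registration window: anaphase not detected")
  unname(-b[1] / b[2])
}

.angle_at <- function(vertex, p1, p2) {
  v1 <- p1 - vertex; v2 <- p2 - vertex
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  acos(min(1, max(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Spindle rotation angle over time
#'
#' The rotation angle is measured at the spindle midpoint (equidistant
#' from the two clusters) between the internalized cluster and the
#' oocyte centroid: about 90 degrees while the spindle lies parallel
#' to the cortex, falling toward 0 as it reorients perpendicular.
#' In/out labels are retrospective: frames before the outcome resolves
#' inherit the final assignment.
#'
#' @param track a `ClusterTrack` (3D, physical units) or `Trajectory`
#'   (2D; centroid defaults to the oocyte centre at the origin).
#' @param centroid oocyte centroid; for a `ClusterTrack` defaults to
#'   the per-frame cell centroid.
#' @param in_index which cluster internalized (1 or 2); defaults to
#'   the object's own label.
#' @return data.frame with columns `t` and `alpha` (degrees, NA where
#'   the midpoint coincides with the centroid or a cluster is missing).
#' @export
rotationAngle <- function(track, centroid = NULL, in_index = NULL) {
  if (is(track, "Trajectory")) {
    fr <- track@frames
    if (is.null(in_index)) in_index <- track@inIndex
    if (is.na(in_index)) in_index <- 1L
    if (is.null(centroid)) centroid <- c(0, 0)
    mx <- (fr$x1x + fr$x2x) / 2; my <- (fr$x1y + fr$x2y) / 2
    cin <- if (in_index == 1L) cbind(fr$x1x, fr$x1y) else cbind(fr$x2x, fr$x2y)
    alpha <- vapply(seq_len(nrow(fr)), function(i)
      .angle_at(c(mx[i], my[i]), cin[i, ], centroid), numeric(1))
    return(data.frame(t = fr$t, alpha = alpha))
  }
  fr <- trackFrames(track)
  if (is.null(in_index)) in_index <- track@inIndex
  if (is.null(in_index) || is.na(in_index)) in_index <- 1L
  alpha <- vapply(seq_len(nrow(fr)), function(i) {
    p1 <- unlist(fr[i, c("c1x", "c1y", "c1z")])
    p2 <- unlist(fr[i, c("c2x", "c2y", "c2z")])
    if (any(!is.finite(p1)) || any(!is.finite(p2))) return(NA_real_)
    mid <- (p1 + p2) / 2
    cen <- if (is.null(centroid))
      unlist(fr[i, c("cellx", "celly", "cellz")]) else centroid
    .angle_at(mid, if (in_index == 1L) p1 else p2, cen)
  }, numeric(1))
  data.frame(t = fr$t, alpha = alpha)
}

#' Spindle spin angle
#'
#' Angular displacement of the spindle midpoint around the oocyte
#' centroid between the start and the end of rotation: the angle at
#' the centroid between the two midpoints. Detects peripheral
#' "spinning" of the spindle without genuine rotation.
#'
#' @param track a `ClusterTrack` or `Trajectory`.
#' @param centroid oocyte centroid (defaults as in [rotationAngle()]).
#' @param t_start,t_end times of the beginning and end of rotation
#'   (nearest recorded frames are used).
#' @return spin angle beta in degrees, in 0..180.
#' @export
spinAngle <- function(track, centroid = NULL, t_start, t_end) {
  mids <- function(tq) {
    if (is(track, "Trajectory")) {
      fr <- track@frames
      i <- which.min(abs(fr$t - tq))
      c((fr$x1x[i] + fr$x2x[i]) / 2, (fr$x1y[i] + fr$x2y[i]) / 2)
    } else {
      fr <- trackFrames(track)
      i <- which.min(abs(fr$t - tq))
      c((fr$c1x[i] + fr$c2x[i]) / 2, (fr$c1y[i] + fr$c2y[i]) / 2,
        (fr$c1z[i] + fr$c2z[i]) / 2)
    }
  }
  if (is.null(centroid))
    centroid <- if (is(track, "Trajectory")) c(0, 0) else {
      fr <- trackFrames(track)
      i <- which.min(abs(fr$t - t_start))
      unlist(fr[i, c("cellx", "celly", "cellz")])
    }
  m1 <- mids(t_start); m2 <- mids(t_end)
  .angle_at(centroid, m1, m2)
}

.fivepl <- function(s, A, B, C, D, E) D + (A - D) / (1 + (s / C)^B)^E

#' Fit a five-parameter logistic to a rotation curve
#'
#' Least-squares fit of `y(t) = D + (A - D)/(1 + (t/C)^B)^E` to the
#' rotation-angle series, used to extract a monotone smoothed rotation
#' profile. The model needs positive times; series whose fit window
#' starts at or below zero are shifted internally and the onset mapped
#' back. Multi-start over the slope parameter (B in 2, 5, 10) with C
#' at mid-window and E = 1; the best converged start by residual sum
#' of squares wins.
#'
#' @param t time vector.
#' @param alpha angle series (degrees).
#' @param window optional length-2 fit window (defaults to the full
#'   span).
#' @param rmse_cap refuse fits with residual RMSE above this value.
#' @param min_span fitted spans (|A - D|) below this are flagged
#'   degenerate and yield `ti = NA`.
#' @return a [RotationFit-class]; errors if no start converges.
#' @export
fitRotationLogistic <- function(t, alpha, window = NULL,
                                rmse_cap = Inf, min_span = 1) {
  ok <- is.finite(t) & is.finite(alpha)
  t <- t[ok]; alpha <- alpha[ok]
  if (is.null(window)) window <- range(t)
  sel <- t >= window[1] & t <= window[2]
  ts <- t[sel]; ys <- alpha[sel]
  if (length(ts) < 8) stop("need at least 8 points in the fit window")
  span <- diff(range(ts))
  # the model needs t > 0; fit in raw time when possible (the family
  # is not closed under translation, so shifting is a last resort for
  # windows that start at or below zero)
  shift <- min(0, window[1] - span / 100)
  s <- ts - shift

  if (diff(range(ys)) < min_span) {
    co <- c(A = mean(ys), B = 1, C = stats::median(s), D = mean(ys), E = 1)
    return(new("RotationFit", coef = co, window = window,
               rmse = stats::sd(ys), ti = NA_real_, degenerate = TRUE,
               extrapolated = FALSE))
  }

  nhead <- max(3L, length(ys) %/% 10L)
  A0 <- mean(utils::head(ys, nhead))
  D0 <- mean(utils::tail(ys, nhead))
  # asymptotes boxed to the observed range plus half a span: keeps the
  # 5% onset anchored to the data while remaining equivariant under
  # affine rescaling of the angle axis
  margin <- 0.5 * diff(range(ys))
  ylo <- min(ys) - margin; yhi <- max(ys) + margin
  tried <- list(); best <- NULL; best_rss <- Inf
  for (B0 in c(2, 5, 10)) {
    st <- list(A = A0, B = B0, C = stats::median(s), D = D0, E = 1)
    tried[[length(tried) + 1]] <- st
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ D + (A - D) / (1 + (s / C)^B)^E,
                        data = data.frame(s = s, y = ys), start = st,
                        lower = c(A = ylo, B = 1e-3, C = 1e-9,
                                  D = ylo, E = 1e-2),
                        upper = c(A = yhi, B = 1e3, C = max(s) * 100,
                                  D = yhi, E = 1e2),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best))
    stop("5PL fit did not converge; tried starts: ",
         paste(vapply(tried, function(x)
           sprintf("B=%g,C=%.3g", x$B, x$C), ""), collapse = "; "))
  co <- stats::coef(best)[c("A", "B", "C", "D", "E")]
  rmse <- sqrt(best_rss / length(ys))
  if (rmse > rmse_cap)
    stop(sprintf("5PL fit RMSE %.3g exceeds cap %.3g", rmse, rmse_cap))
  degen <- abs(co["A"] - co["D"]) < min_span
  ti <- NA_real_; extra <- FALSE
  if (!degen) {
    target <- co["A"] - 0.05 * (co["A"] - co["D"])
    f <- function(si) .fivepl(si, co["A"], co["B"], co["C"], co["D"],
                              co["E"]) - target
    lo <- min(s) * 1e-6; hi <- max(s) * 100
    ti <- tryCatch({
      root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
      root + shift
    }, error = function(e) NA_real_)
    if (is.finite(ti)) extra <- ti < min(ts) || ti > max(ts)
  }
  new("RotationFit", coef = co, window = window, rmse = rmse,
      ti = unname(ti), degenerate = unname(degen), extrapolated = extra)
}

#' Rotation onset time from a logistic fit
#'
#' The onset `t_i` is the time when the fitted rotation curve has
#' completed 5% of its total span between asymptotes; unique by
#' monotonicity of the five-parameter logistic.
#'
#' @param fit a [RotationFit-class].
#' @return `t_i`; NA (with a warning) for degenerate fits.
#' @export
rotationOnset <- function(fit) {
  stopifnot(is(fit, "RotationFit"))
  if (fit@degenerate) {
    warning("degenerate fit (span below threshold): onset undefined")
    return(NA_real_)
  }
  fit@ti
}

#' Early-window in/out cortex-distance ratio
#'
#' Mean over the early analysis window of the internalized cluster's
#' cortex distance divided by the extruded cluster's. A ratio above 1
#' means the eventually extruded cluster sat closer to the cortex
#' before rotation started.
#'
#' @param t time vector.
#' @param d_in,d_out cortex distances of the internalized and extruded
#'   clusters.
#' @param window length-2 early time window.
#' @return the mean ratio; frames with `d_out == 0` are excluded with
#'   a warning.
#' @export
cortexDistanceRatio <- function(t, d_in, d_out, window) {
  sel <- t >= window[1] & t <= window[2] & is.finite(d_in) &
    is.finite(d_out)
  if (any(d_out[sel] <= 0)) {
    warning("frames with zero out-cluster cortex distance excluded")
    sel <- sel & d_out > 0
  }
  if (!any(sel)) stop("empty early window")
  mean(d_in[sel] / d_out[sel])
}

#' Split a population into tertiles of rotation onset
#'
#' Three equiprobable categories of increasing `t_i` by empirical
#' quantiles; group sizes differ by at most one, ties broken by stable
#' input order.
#'
#' @param ti vector of onset times (at least 3 finite values).
#' @return integer vector of category labels 1 (early) to 3 (late),
#'   NA where `ti` is NA.
#' @export
categorizeByOnset <- function(ti) {
  fin <- which(is.finite(ti))
  if (length(fin) < 3) stop("need at least 3 finite onset times")
  if (length(unique(ti[fin])) == 1)
    warning("all onset times equal; tertiles assigned by input order")
  r <- rank(ti[fin], ties.method = "first")
  g <- ceiling(3 * r / length(fin))
  out <- rep(NA_integer_, length(ti))
  out[fin] <- as.integer(g)
  out
}

#' Spindle relocation speed toward the oocyte centroid
#'
#' Least-squares slope of the spindle-midpoint-to-centroid distance
#' inside the analysis window (negative = moving inward), plus a
#' relocated/peripheral classification of the final distance.
#'
#' @param t time (minutes).
#' @param dist midpoint-to-centroid distance (micrometres).
#' @param window analysis window in minutes (default 10 to 50).
#' @param threshold final distance below which the spindle is classed
#'   "relocated" (micrometres).
#' @return list with `slope` (um/min) and `class`.
#' @export
relocationSpeed <- function(t, dist, window = c(10, 50),
                            threshold = 20) {
  sel <- t >= window[1] & t <= window[2] & is.finite(dist)
  if (sum(sel) < 3) stop("need at least 3 points in the analysis window")
  fit <- stats::lm.fit(cbind(1, t[sel]), dist[sel])
  final <- dist[sel][which.max(t[sel])]
  list(slope = unname(fit$coefficients[2]),
       class = if (final < threshold) "relocated" else "peripheral")
}

#' Per-run symmetry-breaking metrics of a simulated trajectory
#'
#' Computes the quantities tabulated by [runEnsemble()]: the rotation
#' onset `ti` from a five-parameter logistic fit of the rotation curve
#' (empirical 5%-of-span crossing as fallback, flagged in
#' `ti_method`), the early-window in/out cortex-distance ratio and the
#' final rotation angle.
#'
#' @param tr a [Trajectory-class].
#' @param early_fraction fraction of `t_max` forming the early window.
#' @param fit_onset attempt the logistic fit (TRUE) or return NA onset.
#' @return list with `ti`, `ti_method`, `inout_ratio`, `final_alpha`.
#' @export
trajMetrics <- function(tr, early_fraction = 1 / 6, fit_onset = TRUE) {
  fr <- tr@frames
  idx <- tr@inIndex
  if (is.na(idx)) idx <- 1L
  d_in <- if (idx == 1L) fr$d1 else fr$d2
  d_out <- if (idx == 1L) fr$d2 else fr$d1
  win <- c(0, early_fraction * tr@params$t_max)
  ratio <- cortexDistanceRatio(fr$t, d_in, d_out, win)

  ti <- NA_real_; method <- "none"
  if (fit_onset && tr@outcome == "broken") {
    fit <- tryCatch(fitRotationLogistic(fr$t, fr$alpha),
                    error = function(e) NULL)
    if (!is.null(fit) && !fit@degenerate && is.finite(fit@ti)) {
      ti <- fit@ti; method <- "logistic5"
    } else {
      a0 <- mean(utils::head(fr$alpha, max(3L, nrow(fr) %/% 20L)))
      span <- a0 - min(fr$alpha)
      if (span > 1) {
        hit <- which(fr$alpha <= a0 - 0.05 * span)
        if (length(hit)) { ti <- fr$t[hit[1]]; method <- "empirical" }
      }
    }
  }
  list(ti = ti, ti_method = method, inout_ratio = ratio,
       final_alpha = fr$alpha[nrow(fr)])
}
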