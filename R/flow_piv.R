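#' PIV parameters
#'
#' Two-pass cross-correlation settings: an 80 px first pass and 40 px
#' second pass at 50% overlap (the alternative coarse preset is
#' 160/80 with 5x5 spatial and 13-point temporal smoothing kernels).
#'
#' @param pass1,pass2 interrogation window sizes in pixels
#'   (`pass2 <= pass1`).
#' @param overlap window overlap fraction (grid spacing =
#'   `pass2 * (1 - overlap)`).
#' @param smooth_space spatial running-average kernel (vectors, odd).
#' @param smooth_time temporal running-average kernel (frames, odd).
#' @param dt_min frame interval in minutes.
#' @param dxy pixel size in micrometres.
#' @param quality_ratio minimum first-to-second correlation peak
#'   ratio; below it a vector is invalidated.
#' @param min_mask_frac minimum fraction of a window inside the cell
#'   mask for the vector to be computed.
#' @return named list of class `pivParams`.
#' @export
pivParams <- function(pass1 = 80, pass2 = 40, overlap = 0.5,
                      smooth_space = 3, smooth_time = 9, dt_min = 1,
                      dxy = 1, quality_ratio = 1.2,
                      min_mask_frac = 0.5) {
  stopifnot(pass2 <= pass1, pass2 >= 8, overlap >= 0, overlap < 1,
            smooth_space %% 2 == 1, smooth_time %% 2 == 1,
            dt_min > 0, dxy > 0, quality_ratio >= 1)
  p <- list(pass1 = pass1, pass2 = pass2, overlap = overlap,
            smooth_space = smooth_space, smooth_time = smooth_time,
            dt_min = dt_min, dxy = dxy, quality_ratio = quality_ratio,
            min_mask_frac = min_mask_frac)
  class(p) <- c("pivParams", "list")
  p
}

# circular FFT cross-correlation of two equally sized windows,
# mean-subtracted; returns the correlation plane with zero shift at
# the centre
.xcorr <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  n <- dim(a)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b),
                      inverse = TRUE)) / length(a)
  # reorder so displacement 0 sits at index (n/2+1, n/2+1)
  sh <- n %/% 2
  cc[c((sh[1] + 1):n[1], 1:sh[1]), c((sh[2] + 1):n[2], 1:sh[2])]
}

.peak_subpixel <- function(cc, max_disp, quality_ratio) {
  n <- dim(cc)
  c0 <- n %/% 2 + 1
  ys <- (c0[1] - max_disp):(c0[1] + max_disp)
  xs <- (c0[2] - max_disp):(c0[2] + max_disp)
  sub <- cc[ys, xs]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  py <- ys[pk[1]]; px <- xs[pk[2]]
  # quality: first to second peak (outside the 3x3 around the first)
  sub2 <- sub
  y0 <- max(1, pk[1] - 1):min(nrow(sub), pk[1] + 1)
  x0 <- max(1, pk[2] - 1):min(ncol(sub), pk[2] + 1)
  sub2[y0, x0] <- -Inf
  p2 <- max(sub2)
  ok <- is.finite(p2) && p2 > 0 && max(sub) / p2 >= quality_ratio ||
    !is.finite(p2)
  if (max(sub) <= 0) ok <- FALSE
  # 3-point Gaussian sub-pixel fit per axis
  gfit <- function(cm, cc_, cp) {
    cm <- max(cm, 1e-12); cc_ <- max(cc_, 1e-12); cp <- max(cp, 1e-12)
    den <- 2 * (log(cm) + log(cp) - 2 * log(cc_))
    if (den == 0) return(0)
    d <- (log(cm) - log(cp)) / den
    max(-0.5, min(0.5, d))
  }
  dy <- if (py > 1 && py < n[1])
    gfit(cc[py - 1, px], cc[py, px], cc[py + 1, px]) else 0
  dx <- if (px > 1 && px < n[2])
    gfit(cc[py, px - 1], cc[py, px], cc[py, px + 1]) else 0
  list(u = px - c0[2] + dx, v = py - c0[1] + dy, valid = ok)
}

.window_at <- function(img, cy, cx, half) {
  ys <- (cy - half):(cy + half - 1)
  xs <- (cx - half):(cx + half - 1)
  if (min(ys) < 1 || min(xs) < 1 || max(ys) > nrow(img) ||
      max(xs) > ncol(img)) return(NULL)
  img[ys, xs]
}

#' Two-pass cross-correlation PIV
#'
#' Estimates per-frame-pair velocity fields from a movie: a coarse
#' first pass measures integer window shifts, a second pass
#' re-correlates smaller windows offset by the pass-1 shift, and the
#' correlation peak is refined to sub-pixel precision with a
#' three-point Gaussian fit per axis. Vectors centred outside the
#' cell mask, in windows with insufficient mask coverage, with flat
#' correlation planes or with a poor first-to-second peak ratio are
#' invalidated.
#'
#' @param movie array (frames, y, x).
#' @param mask logical (y, x) cell mask; NULL disables masking.
#' @param pp a [pivParams()] list.
#' @return a [FlowField-class] with velocities in px/frame.
#' @export
pivTwoPass <- function(movie, mask = NULL, pp = pivParams()) {
  nT <- dim(movie)[1]; ny <- dim(movie)[2]; nx <- dim(movie)[3]
  stopifnot(nT >= 2)
  if (is.null(mask)) mask <- matrix(TRUE, ny, nx)
  h1 <- pp$pass1 %/% 2; h2 <- pp$pass2 %/% 2
  step <- max(1, round(pp$pass2 * (1 - pp$overlap)))
  gy <- seq(h1 + 1, ny - h1 + 1, by = step)
  gx <- seq(h1 + 1, nx - h1 + 1, by = step)
  if (!length(gy) || !length(gx))
    stop("frame too small for the pass-1 window")
  u <- array(NA_real_, dim = c(nT - 1, length(gy), length(gx)))
  v <- u
  valid <- array(FALSE, dim = dim(u))
  for (f in seq_len(nT - 1)) {
    A <- movie[f, , ]; B <- movie[f + 1, , ]
    for (iy in seq_along(gy)) for (ix in seq_along(gx)) {
      cy <- gy[iy]; cx <- gx[ix]
      if (!mask[cy, cx]) next
      w1a <- .window_at(A, cy, cx, h1)
      w1b <- .window_at(B, cy, cx, h1)
      if (is.null(w1a) || is.null(w1b)) next
      msk <- .window_at(mask * 1, cy, cx, h2)
      if (mean(msk) < pp$min_mask_frac) next
      if (stats::sd(w1a) == 0 || stats::sd(w1b) == 0) next
      p1 <- .peak_subpixel(.xcorr(w1a, w1b), max_disp = h1 %/% 2,
                           quality_ratio = 1)
      off_x <- round(p1$u); off_y <- round(p1$v)
      w2a <- .window_at(A, cy, cx, h2)
      w2b <- .window_at(B, cy + off_y, cx + off_x, h2)
      if (is.null(w2b)) { w2b <- w2a; off_x <- 0; off_y <- 0 }
      if (stats::sd(w2a) == 0 || stats::sd(w2b) == 0) next
      p2 <- .peak_subpixel(.xcorr(w2a, w2b), max_disp = h2 %/% 2,
                           quality_ratio = pp$quality_ratio)
      u[f, iy, ix] <- off_x + p2$u
      v[f, iy, ix] <- off_y + p2$v
      valid[f, iy, ix] <- p2$valid
    }
  }
  new("FlowField", u = u, v = v, gx = as.numeric(gx),
      gy = as.numeric(gy), valid = valid, dtMin = pp$dt_min,
      dxy = pp$dxy)
}

#' Mask-aware running-average smoothing of a flow field
#'
#' Component-wise running average over valid neighbours, first with a
#' `smooth_space` x `smooth_space` kernel within each frame, then
#' with a `smooth_time`-point kernel along frames. Invalid vectors
#' are filled from the neighbourhood when at least half the kernel is
#' valid; smoothing is linear and leaves constant fields unchanged.
#'
#' @param ff a [FlowField-class].
#' @param pp a [pivParams()] list.
#' @return a smoothed [FlowField-class].
#' @export
smoothField <- function(ff, pp = pivParams()) {
  ks <- pp$smooth_space %/% 2
  kt <- pp$smooth_time %/% 2
  dims <- dim(ff@u)
  sm_space <- function(a, val) {
    out <- a; outv <- val
    for (f in seq_len(dims[1])) {
      for (iy in seq_len(dims[2])) for (ix in seq_len(dims[3])) {
        ys <- max(1, iy - ks):min(dims[2], iy + ks)
        xs <- max(1, ix - ks):min(dims[3], ix + ks)
        vals <- a[f, ys, xs]; ok <- val[f, ys, xs]
        if (val[f, iy, ix]) {
          out[f, iy, ix] <- mean(vals[ok])
        } else if (mean(ok) >= 0.5) {
          out[f, iy, ix] <- mean(vals[ok]); outv[f, iy, ix] <- TRUE
        }
      }
    }
    list(a = out, v = outv)
  }
  su <- sm_space(ff@u, ff@valid); sv <- sm_space(ff@v, ff@valid)
  val2 <- su$v & sv$v
  uu <- su$a; vv <- sv$a
  if (kt > 0 && dims[1] > 1) {
    u3 <- uu; v3 <- vv; val3 <- val2
    for (f in seq_len(dims[1])) {
      fs <- max(1, f - kt):min(dims[1], f + kt)
      for (iy in seq_len(dims[2])) for (ix in seq_len(dims[3])) {
        ok <- val2[fs, iy, ix]
        if (!any(ok)) { val3[f, iy, ix] <- FALSE; next }
        u3[f, iy, ix] <- mean(uu[fs, iy, ix][ok])
        v3[f, iy, ix] <- mean(vv[fs, iy, ix][ok])
      }
    }
    uu <- u3; vv <- v3; val2 <- val3
  }
  new("FlowField", u = uu, v = vv, gx = ff@gx, gy = ff@gy,
      valid = val2, dtMin = ff@dtMin, dxy = ff@dxy)
}

#' Axial 1D velocity series
#'
#' Projects the flow field onto the polarity axis inside a central
#' region of interest and averages per frame. With the axis pointing
#' from the polarized cortical domain toward the cell centre,
#' positive values mean inverted (centerward) flow and negative
#' values metaphase-like flow toward the polarized domain.
#'
#' @param ff a [FlowField-class].
#' @param axis length-2 vector (image x, y components) pointing from
#'   the polarized domain toward the cell centre; normalized
#'   internally.
#' @param roi list with `center` (x, y, px) and `radius` (px)
#'   defining the central analysis region.
#' @param units `"um_min"` (default) scales px/frame by
#'   `dxy / dt_min`; `"px_frame"` keeps pixel units.
#' @return data.frame (frame, t_min, velocity); errors if the ROI
#'   contains no valid grid points.
#' @export
axialVelocity <- function(ff, axis, roi,
                          units = c("um_min", "px_frame")) {
  units <- match.arg(units)
  ax <- axis / sqrt(sum(axis^2))
  gxm <- matrix(rep(ff@gx, each = length(ff@gy)), length(ff@gy))
  gym <- matrix(rep(ff@gy, length(ff@gx)), length(ff@gy))
  inroi <- (gxm - roi$center[1])^2 + (gym - roi$center[2])^2 <=
    roi$radius^2
  if (!any(inroi)) stop("empty PIV ROI")
  nT <- dim(ff@u)[1]
  out <- numeric(nT)
  for (f in seq_len(nT)) {
    ok <- inroi & ff@valid[f, , ]
    if (!any(ok)) { out[f] <- NA_real_; next }
    out[f] <- mean(ff@u[f, , ][ok] * ax[1] + ff@v[f, , ][ok] * ax[2])
  }
  scale <- if (units == "um_min") ff@dxy / ff@dtMin else 1
  data.frame(frame = seq_len(nT),
             t_min = (seq_len(nT) - 0.5) * ff@dtMin,
             velocity = out * scale)
}

#' Top-decile maximum velocity in an analysis window
#'
#' Mean of the `top` fraction (default 10%) largest velocities inside
#' the analysis window (default 10 to 50 minutes).
#'
#' @param t time vector (minutes).
#' @param velocity velocity series.
#' @param window length-2 window (minutes).
#' @param top fraction of largest values averaged.
#' @return the summary scalar.
#' @export
maxVelocity <- function(t, velocity, window = c(10, 50), top = 0.10) {
  sel <- t >= window[1] & t <= window[2] & is.finite(velocity)
  if (!any(sel)) stop("empty analysis window")
  vals <- sort(velocity[sel], decreasing = TRUE)
  mean(vals[seq_len(max(1L, ceiling(top * length(vals))))])
}
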