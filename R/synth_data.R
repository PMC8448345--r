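#' Rendering parameters for synthetic fluorescence stacks
#'
#' Controls the synthetic 4D DNA-channel generator: geometry of the
#' dim cytoplasmic ball, the bright Gaussian DNA blobs, the
#' depth-dependent brightness attenuation along Z that confocal stacks
#' of large oocytes show, and the noise model (Gaussian read noise
#' plus an intensity-proportional variance term). The default
#' z-spacing of 3.2 um matches 20-plane confocal stacks of mouse
#' oocytes; xy pixels default to 1 um.
#'
#' @param nx,ny,nz,nt image shape (X, Y, Z planes, time points).
#' @param dz,dxy voxel sizes in micrometres.
#' @param cell_center length-3 (x, y, z) centre of the cell in um;
#'   default image centre.
#' @param cell_radius cell radius in um.
#' @param cluster_sd Gaussian SD of a DNA blob in um (isotropic in
#'   physical units, sampled on the anisotropic voxel grid).
#' @param cluster_peak peak blob intensity (arbitrary units).
#' @param cyto_base cytoplasm base intensity.
#' @param z_decay per-slice exponential attenuation coefficient
#'   (slice z is scaled by `exp(-z_decay * (z - 1))`).
#' @param noise_sd Gaussian read-noise SD.
#' @param shot_scale variance of the intensity-proportional noise term
#'   per intensity unit (0 disables).
#' @param seed RNG seed for the noise.
#' @return named list of class `renderParams`.
#' @export
renderParams <- function(nx = 80, ny = 80, nz = 20, nt = 1,
                         dz = 3.2, dxy = 1.0, cell_center = NULL,
                         cell_radius = 25, cluster_sd = 2.5,
                         cluster_peak = 50, cyto_base = 5,
                         z_decay = 0, noise_sd = 0, shot_scale = 0,
                         seed = 1L) {
  if (is.null(cell_center))
    cell_center <- c((nx - 1) * dxy / 2, (ny - 1) * dxy / 2,
                     (nz - 1) * dz / 2)
  stopifnot(dz > 0, dxy > 0, cell_radius > 0, cluster_sd > 0,
            cluster_peak >= 0, cyto_base >= 0, z_decay >= 0,
            z_decay < 1, noise_sd >= 0, shot_scale >= 0)
  # cell must fit in the xy frame
  if (cell_center[1] - cell_radius < 0 ||
      cell_center[1] + cell_radius > (nx - 1) * dxy ||
      cell_center[2] - cell_radius < 0 ||
      cell_center[2] + cell_radius > (ny - 1) * dxy)
    stop("cell does not fit inside the xy frame")
  p <- list(nx = nx, ny = ny, nz = nz, nt = nt, dz = dz, dxy = dxy,
            cell_center = cell_center, cell_radius = cell_radius,
            cluster_sd = cluster_sd, cluster_peak = cluster_peak,
            cyto_base = cyto_base, z_decay = z_decay,
            noise_sd = noise_sd, shot_scale = shot_scale,
            seed = as.integer(seed))
  class(p) <- c("renderParams", "list")
  p
}

#' Positions of a simulated trajectory in image coordinates
#'
#' Maps the 2D model coordinates (units of the oocyte radius, origin
#' at the cell centre) of a [Trajectory-class] onto the physical image
#' frame of a [renderParams()] set: xy scaled by the cell radius, z at
#' the equatorial plane. Frames are sampled evenly down to `nt` time
#' points.
#'
#' @param traj a [Trajectory-class].
#' @param rp a [renderParams()] list.
#' @return data.frame (frame, t, c1x..c1z, c2x..c2z) in micrometres.
#' @export
trajToPaths <- function(traj, rp) {
  fr <- trajFrames(traj)
  idx <- round(seq(1, nrow(fr), length.out = rp$nt))
  R <- trajParams(traj)$R_ovo
  s <- rp$cell_radius / R
  data.frame(frame = seq_len(rp$nt), t = fr$t[idx],
             c1x = rp$cell_center[1] + fr$x1x[idx] * s,
             c1y = rp$cell_center[2] + fr$x1y[idx] * s,
             c1z = rp$cell_center[3],
             c2x = rp$cell_center[1] + fr$x2x[idx] * s,
             c2y = rp$cell_center[2] + fr$x2y[idx] * s,
             c2z = rp$cell_center[3])
}

#' Render a synthetic 4D DNA-channel stack with ground truth
#'
#' Renders two DNA clusters as isotropic 3D Gaussian blobs moving
#' along prescribed paths inside a dim cytoplasmic ball, applies the
#' per-slice exponential depth attenuation, and adds read and
#' intensity-proportional noise. Stands in for H2B-labelled chromatin
#' movies with known ground truth.
#'
#' @param paths either a [Trajectory-class] (mapped through
#'   [trajToPaths()]) or a data.frame as returned by it; cluster
#'   columns may contain NA to drop a cluster from a frame.
#' @param rp a [renderParams()] list.
#' @return list with `stack` (an [ImageStack-class]) and `truth`
#'   (data.frame of true centroids in um plus cell centre and radius
#'   as attributes).
#' @examples
#' rp <- renderParams(nx = 40, ny = 40, nz = 8, cell_radius = 15)
#' paths <- data.frame(frame = 1, t = 0, c1x = 12, c1y = 20, c1z = 11.2,
#'                     c2x = 28, c2y = 20, c2z = 11.2)
#' st <- renderStack(paths, rp)
#' @export
renderStack <- function(paths, rp = renderParams()) {
  if (is(paths, "Trajectory")) paths <- trajToPaths(paths, rp)
  stopifnot(nrow(paths) == rp$nt)
  # all cluster centres must lie inside the cell
  for (pre in c("c1", "c2")) {
    px <- paths[[paste0(pre, "x")]]; py <- paths[[paste0(pre, "y")]]
    pz <- paths[[paste0(pre, "z")]]
    ok <- !is.na(px)
    rr <- sqrt((px[ok] - rp$cell_center[1])^2 +
                 (py[ok] - rp$cell_center[2])^2 +
                 (pz[ok] - rp$cell_center[3])^2)
    if (any(rr > rp$cell_radius))
      stop("cluster path exits the cell")
  }
  set.seed(rp$seed)
  xs <- (seq_len(rp$nx) - 1) * rp$dxy
  ys <- (seq_len(rp$ny) - 1) * rp$dxy
  zs <- (seq_len(rp$nz) - 1) * rp$dz
  arr <- array(0, dim = c(rp$nt, rp$nz, rp$ny, rp$nx))
  # squared xy distance from cell centre, reused per slice
  dx2 <- outer((ys - rp$cell_center[2])^2, (xs - rp$cell_center[1])^2, "+")
  for (ti in seq_len(rp$nt)) {
    for (zi in seq_len(rp$nz)) {
      dz2 <- (zs[zi] - rp$cell_center[3])^2
      plane <- ifelse(dx2 + dz2 <= rp$cell_radius^2, rp$cyto_base, 0)
      for (pre in c("c1", "c2")) {
        cx <- paths[[paste0(pre, "x")]][ti]
        if (is.na(cx)) next
        cy <- paths[[paste0(pre, "y")]][ti]
        cz <- paths[[paste0(pre, "z")]][ti]
        g <- rp$cluster_peak *
          exp(-(outer((ys - cy)^2, (xs - cx)^2, "+") +
                  (zs[zi] - cz)^2) / (2 * rp$cluster_sd^2))
        plane <- plane + g
      }
      plane <- plane * exp(-rp$z_decay * (zi - 1))
      if (rp$noise_sd > 0 || rp$shot_scale > 0) {
        sdv <- sqrt(rp$noise_sd^2 + rp$shot_scale * plane)
        plane <- plane + stats::rnorm(length(plane), 0, sdv)
        plane[plane < 0] <- 0
      }
      arr[ti, zi, , ] <- plane
    }
  }
  truth <- paths
  attr(truth, "cell_center") <- rp$cell_center
  attr(truth, "cell_radius") <- rp$cell_radius
  list(stack = new("ImageStack", data = arr, dz = rp$dz, dxy = rp$dxy,
                   channel = "DNA"),
       truth = truth)
}

#' Synthetic cortical polarity image
#'
#' A 2D circular cell whose cortical band carries an intensity profile
#' made of a cap (exponential decay with distance to the nearest DNA
#' cluster, emulating chromatin-proximal F-actin enrichment) plus a
#' ring (Gaussian bump peaked at a set distance from the clusters,
#' emulating the myosin-II ring around the cap).
#'
#' @param nx,ny image size in pixels.
#' @param cell_center,cell_radius cell geometry in pixels (defaults:
#'   image centre, 40% of the smaller dimension).
#' @param band_width cortical band thickness in pixels.
#' @param clusters 2x2 matrix of cluster (x, y) pixel positions; a
#'   single row gives a one-cluster image.
#' @param base base cortical intensity.
#' @param cap_amp,cap_lambda cap amplitude and decay length (px).
#' @param ring_amp,ring_d,ring_w ring amplitude, peak distance (px)
#'   and Gaussian width (px).
#' @param cyto_int cytoplasm intensity inside the cell.
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed.
#' @return list with `image` (ny x nx matrix), `mask` (logical cell
#'   mask) and `truth` (list of the profile parameters).
#' @export
makeCortexImage <- function(nx = 200, ny = 200, cell_center = NULL,
                            cell_radius = NULL, band_width = 15,
                            clusters = NULL, base = 10, cap_amp = 0,
                            cap_lambda = 30, ring_amp = 0,
                            ring_d = 20, ring_w = 6, cyto_int = 2,
                            noise_sd = 0, seed = 1L) {
  if (is.null(cell_center)) cell_center <- c(nx, ny) / 2
  if (is.null(cell_radius)) cell_radius <- 0.4 * min(nx, ny)
  if (is.null(clusters))
    clusters <- rbind(c(cell_center[1] - 10,
                        cell_center[2] - cell_radius + 12),
                      c(cell_center[1] + 10,
                        cell_center[2] - cell_radius + 12))
  clusters <- rbind(clusters)
  if (ring_amp > 0 && ring_d >= pi * cell_radius)
    stop("ring peak distance exceeds the half-perimeter of the band")
  set.seed(seed)
  xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yg <- matrix(rep(seq_len(ny), nx), ny, nx)
  rr <- sqrt((xg - cell_center[1])^2 + (yg - cell_center[2])^2)
  mask <- rr <= cell_radius
  band <- mask & rr >= cell_radius - band_width
  dmin <- matrix(Inf, ny, nx)
  for (i in seq_len(nrow(clusters)))
    dmin <- pmin(dmin, sqrt((xg - clusters[i, 1])^2 +
                              (yg - clusters[i, 2])^2))
  img <- matrix(0, ny, nx)
  img[mask] <- cyto_int
  prof <- base + cap_amp * exp(-dmin / cap_lambda) +
    ring_amp * exp(-(dmin - ring_d)^2 / (2 * ring_w^2))
  img[band] <- prof[band]
  if (noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, noise_sd)
    img[img < 0] <- 0
  }
  list(image = img, mask = mask,
       truth = list(cell_center = cell_center,
                    cell_radius = cell_radius, clusters = clusters,
                    band_width = band_width, base = base,
                    cap_amp = cap_amp, cap_lambda = cap_lambda,
                    ring_amp = ring_amp, ring_d = ring_d,
                    ring_w = ring_w))
}

.flow_fun <- function(flow) {
  if (is.function(flow)) return(flow)
  switch(flow$type,
    uniform = function(x, y, t) {
      v <- if (!is.null(flow$switch_t) && t >= flow$switch_t)
        flow$v2 else flow$v
      cbind(rep(v[1], length(x)), rep(v[2], length(x)))
    },
    radial = function(x, y, t) {
      dx <- x - flow$center[1]; dy <- y - flow$center[2]
      r <- pmax(sqrt(dx^2 + dy^2), 1e-9)
      # rate > 0: source (outward); rate < 0: sink (inward)
      cbind(flow$rate * dx / r, flow$rate * dy / r)
    },
    stop("unknown flow type: ", flow$type))
}

#' Synthetic speckle movie advected by a prescribed flow
#'
#' Seeds random speckles inside a circular cell and advects their
#' positions exactly with the prescribed flow, re-rendering each frame
#' as Gaussian spots. Emulates the brightfield cytoplasmic granularity
#' that PIV tracks, with an analytic ground-truth flow.
#'
#' @param nx,ny frame size (px).
#' @param n_frames number of frames.
#' @param flow a flow spec: `list(type = "uniform", v = c(ux, uy))`
#'   (optionally `v2` and `switch_t` for a programmed reversal),
#'   `list(type = "radial", center =, rate =)` (px/frame, negative =
#'   sink), or a function `(x, y, t) -> cbind(u, v)`.
#' @param density speckles per pixel of cell area.
#' @param speckle_sd Gaussian spot SD (px).
#' @param cell_center,cell_radius cell geometry (defaults: centre,
#'   45% of the smaller dimension).
#' @param max_window the pass-2 PIV window the movie is intended for;
#'   per-frame displacements above a quarter of it raise an error
#'   (correlation would alias).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return list with `movie` (array frames x ny x nx), `mask` (cell
#'   disc), `flow` (the flow function) and `truthAt(gx, gy, t)`
#'   returning the analytic flow on grid points.
#' @export
makeSpeckleMovie <- function(nx = 240, ny = 240, n_frames = 20,
                             flow = list(type = "uniform", v = c(3, 0)),
                             density = 0.05, speckle_sd = 1,
                             cell_center = NULL, cell_radius = NULL,
                             max_window = 40, noise_sd = 0,
                             seed = 1L) {
  if (is.null(cell_center)) cell_center <- c(nx, ny) / 2
  if (is.null(cell_radius)) cell_radius <- 0.45 * min(nx, ny)
  ffun <- .flow_fun(flow)
  set.seed(seed)
  n_sp <- round(density * pi * cell_radius^2)
  th <- stats::runif(n_sp, 0, 2 * pi)
  rad <- cell_radius * sqrt(stats::runif(n_sp))
  px <- cell_center[1] + rad * cos(th)
  py <- cell_center[2] + rad * sin(th)
  amp <- stats::runif(n_sp, 0.5, 1)

  xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yg <- matrix(rep(seq_len(ny), nx), ny, nx)
  mask <- (xg - cell_center[1])^2 + (yg - cell_center[2])^2 <=
    cell_radius^2

  render <- function(x, y) {
    img <- matrix(0, ny, nx)
    ix <- round(x); iy <- round(y)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    for (i in which(ok))
      img[iy[i], ix[i]] <- img[iy[i], ix[i]] + amp[i]
    as.matrix(EBImage::gblur(EBImage::Image(img), sigma = speckle_sd))
  }

  movie <- array(0, dim = c(n_frames, ny, nx))
  for (f in seq_len(n_frames)) {
    movie[f, , ] <- render(px, py)
    v <- ffun(px, py, f)
    if (max(abs(v), na.rm = TRUE) > max_window / 4)
      stop("per-frame displacement exceeds a quarter of the PIV window; ",
           "use larger interrogation windows")
    px <- px + v[, 1]; py <- py + v[, 2]
  }
  if (noise_sd > 0) {
    movie <- movie + stats::rnorm(length(movie), 0, noise_sd)
    movie[movie < 0] <- 0
  }
  list(movie = movie, mask = mask, flow = ffun,
       truthAt = function(gx, gy, t) {
         g <- expand.grid(y = gy, x = gx)
         v <- ffun(g$x, g$y, t)
         list(u = matrix(v[, 1], length(gy), length(gx)),
              v = matrix(v[, 2], length(gy), length(gx)))
       })
}
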