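#' Cortical band of a 2D cell mask
#'
#' Extracts the pixels within `width/2` of the cell outline (a
#' morphological ring following the outline, the 2D analogue of a
#' 10- to 20-pixel-wide line selection) and parameterises them by
#' arclength along the ordered boundary. The arclength origin is
#' placed at the boundary point equidistant from the two DNA clusters
#' on the cluster-proximal side, so profiles from different cells are
#' centred on the polarized domain.
#'
#' @param mask logical matrix (rows = y, columns = x), a single
#'   simply-connected cell.
#' @param width band thickness in pixels (3 to 50).
#' @param clusters 2x2 matrix of cluster (x, y) pixel coordinates
#'   used to centre the arclength origin; NULL keeps the raw
#'   traversal origin.
#' @return list with `band` (data.frame x, y, arclength, dist_out —
#'   signed distance is not kept, only pixels), `outline` (ordered
#'   boundary polygon with arclength) and `perimeter`.
#' @export
corticalBand <- function(mask, width = 15, clusters = NULL) {
  stopifnot(width >= 3, width <= 50)
  img <- EBImage::Image(mask * 1)
  lab <- EBImage::bwlabel(img)
  if (max(lab) != 1) stop("mask must contain exactly one object")
  filled <- EBImage::fillHull(img)
  if (sum(filled > 0) != sum(mask))
    stop("mask is not simply connected (holes present)")
  # transpose so EBImage's (x, y) match the matrix (col, row) layout
  oc <- EBImage::ocontour(EBImage::bwlabel(
    EBImage::Image(t(mask) * 1)))[[1]]
  oc <- oc + 1 # ordered boundary polygon, (x, y), now 1-based
  # circular moving average removes the staircase bias of the digital
  # contour, which would otherwise inflate the perimeter by about 5%
  k <- 5
  n <- nrow(oc)
  if (n > 2 * k) {
    idx <- outer(seq_len(n), -k:k, "+")
    idx <- (idx - 1) %% n + 1
    oc <- cbind(rowMeans(matrix(oc[idx, 1], n)),
                rowMeans(matrix(oc[idx, 2], n)))
  }
  segs <- sqrt(rowSums((oc - oc[c(2:nrow(oc), 1), ])^2))
  perim <- sum(segs)
  arc <- c(0, cumsum(segs))[seq_len(nrow(oc))]

  # the band follows the outline on the inside of the cell, where the
  # cortical signal lives, to the full selection width
  din <- as.matrix(EBImage::distmap(img)) # distance to background
  sel <- which(mask & din <= width, arr.ind = TRUE)
  bx <- sel[, 2]; by <- sel[, 1]

  # nearest outline vertex gives each band pixel its arclength
  nearest <- integer(nrow(sel))
  for (i in seq_along(nearest))
    nearest[i] <- which.min((oc[, 1] - bx[i])^2 + (oc[, 2] - by[i])^2)
  arcpix <- arc[nearest]

  origin <- 0
  if (!is.null(clusters)) {
    d1 <- sqrt((oc[, 1] - clusters[1, 1])^2 + (oc[, 2] - clusters[1, 2])^2)
    d2 <- sqrt((oc[, 1] - clusters[2, 1])^2 + (oc[, 2] - clusters[2, 2])^2)
    eq <- abs(d1 - d2)
    # among near-equidistant vertices pick the cluster-proximal one
    cand <- which(eq <= min(eq) + 1)
    o <- cand[which.min((d1 + d2)[cand])]
    origin <- arc[o]
  }
  arcpix <- (arcpix - origin) %% perim
  list(band = data.frame(x = bx, y = by, arclength = arcpix),
       outline = data.frame(x = oc[, 1], y = oc[, 2],
                            arclength = (arc - origin) %% perim),
       perimeter = perim)
}

#' Euclidean distance map from a point
#'
#' Image of per-pixel Euclidean distances to a reference point (for
#' instance a DNA cluster centroid), in physical units.
#'
#' @param centroid length-2 (x, y) in pixels.
#' @param shape length-2 (ny, nx) output size.
#' @param scale pixel size (um per px); 1 keeps pixel units.
#' @return ny x nx matrix of distances.
#' @export
distanceMap <- function(centroid, shape, scale = 1) {
  if (centroid[1] < 1 || centroid[1] > shape[2] ||
      centroid[2] < 1 || centroid[2] > shape[1])
    stop("centroid outside the frame")
  xg <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1])
  yg <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1])
  sqrt((xg - centroid[1])^2 + (yg - centroid[2])^2) * scale
}

#' Cortical intensity as a function of distance to the DNA clusters
#'
#' Normalizes the band intensities to their own mean, bins them by
#' the Euclidean distance to the cluster centroid(s) and extracts the
#' peak distance as the argmax of the moving-average-smoothed binned
#' curve. Empty bins are marked missing and excluded from the argmax.
#'
#' @param image intensity matrix.
#' @param band band data.frame from [corticalBand()].
#' @param edm distance map (same shape as `image`), e.g. from
#'   [distanceMap()] or a pixel-wise minimum over two maps.
#' @param bin_width distance bin width (px).
#' @param smooth_window moving-average window (bins, odd).
#' @return a [CortexProfile-class].
#' @export
intensityVsDistance <- function(image, band, edm, bin_width = 1,
                                smooth_window = 3) {
  stopifnot(smooth_window %% 2 == 1)
  idx <- cbind(band$y, band$x)
  ints <- image[idx]
  m <- mean(ints)
  if (m <= 0) stop("non-positive mean band intensity")
  ints <- ints / m
  dists <- edm[idx]
  breaks <- seq(0, max(dists) + bin_width, by = bin_width)
  bin <- cut(dists, breaks, include.lowest = TRUE, labels = FALSE)
  curve <- data.frame(
    dist = (breaks[-length(breaks)] + breaks[-1]) / 2,
    intensity = as.numeric(tapply(ints, factor(bin,
      levels = seq_len(length(breaks) - 1)), mean)),
    n = as.numeric(table(factor(bin,
      levels = seq_len(length(breaks) - 1)))))
  sm <- stats::filter(curve$intensity, rep(1 / smooth_window,
                                           smooth_window), sides = 2)
  sm <- as.numeric(sm)
  # ends and empty bins fall back to the raw values
  sm[is.na(sm)] <- curve$intensity[is.na(sm)]
  peak <- curve$dist[which.max(sm)]
  bandout <- data.frame(x = band$x, y = band$y,
                        arclength = band$arclength, intensity = ints,
                        dist1 = dists, dist2 = dists)
  new("CortexProfile", band = bandout, curve = curve,
      peakDist = peak)
}

#' Time-resolved cortical polarity maps and 1D summaries
#'
#' Builds time x arclength maps of normalized cortical intensity and
#' of distance to the nearest DNA cluster, plus per-cluster 1D
#' series: the polarity level `F` of a cluster is the mean normalized
#' intensity of the 25% of band pixels closest to it, and its cortex
#' distance the mean of the 1% closest band pixels.
#'
#' @param frames list of intensity matrices (one per time point).
#' @param masks list of logical cell masks.
#' @param clusters list of 2x2 matrices of cluster (x, y) positions
#'   per frame (row 1 = internalized cluster, row 2 = extruded); NA
#'   rows yield missing summaries.
#' @param width band width (px).
#' @param arc_bins number of arclength bins for the maps.
#' @param f_frac fraction of closest band pixels averaged for the
#'   intensity level (default 25%).
#' @param d_frac fraction for the distance summary (default 1%).
#' @return list with `map_intensity`, `map_distance` (time x bin
#'   matrices) and `summary` (data.frame frame, F_in, F_out, d_in,
#'   d_out).
#' @export
polarityMaps <- function(frames, masks, clusters, width = 15,
                         arc_bins = 90, f_frac = 0.25,
                         d_frac = 0.01) {
  nT <- length(frames)
  stopifnot(length(masks) == nT, length(clusters) == nT)
  map_i <- matrix(NA_real_, nT, arc_bins)
  map_d <- matrix(NA_real_, nT, arc_bins)
  summ <- data.frame(frame = seq_len(nT), F_in = NA_real_,
                     F_out = NA_real_, d_in = NA_real_,
                     d_out = NA_real_)
  for (f in seq_len(nT)) {
    cl <- clusters[[f]]
    if (is.null(cl) || any(!is.finite(cl))) next
    cb <- corticalBand(masks[[f]], width, clusters = cl)
    idx <- cbind(cb$band$y, cb$band$x)
    ints <- frames[[f]][idx]
    ints <- ints / mean(ints)
    d1 <- sqrt((cb$band$x - cl[1, 1])^2 + (cb$band$y - cl[1, 2])^2)
    d2 <- sqrt((cb$band$x - cl[2, 1])^2 + (cb$band$y - cl[2, 2])^2)
    # arclength recentred to -perim/2..perim/2 around the origin
    arc <- cb$band$arclength
    arc <- ifelse(arc > cb$perimeter / 2, arc - cb$perimeter, arc)
    bins <- cut(arc, seq(-cb$perimeter / 2, cb$perimeter / 2,
                         length.out = arc_bins + 1), labels = FALSE,
                include.lowest = TRUE)
    map_i[f, ] <- as.numeric(tapply(ints,
      factor(bins, levels = seq_len(arc_bins)), mean))
    map_d[f, ] <- as.numeric(tapply(pmin(d1, d2),
      factor(bins, levels = seq_len(arc_bins)), mean))
    kf <- max(1L, ceiling(f_frac * length(ints)))
    kd <- max(1L, ceiling(d_frac * length(ints)))
    summ$F_in[f] <- mean(ints[order(d1)[seq_len(kf)]])
    summ$F_out[f] <- mean(ints[order(d2)[seq_len(kf)]])
    summ$d_in[f] <- mean(sort(d1)[seq_len(kd)])
    summ$d_out[f] <- mean(sort(d2)[seq_len(kd)])
  }
  list(map_intensity = map_i, map_distance = map_d, summary = summ)
}
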