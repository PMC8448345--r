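#' Segmentation parameters
#'
#' Settings of the 3D gray-level segmentation of the cell outline and
#' the DNA clusters. Thresholds are adaptive per Z slice to cope with
#' the brightness reduction in the deeper part of confocal stacks:
#' each slice gets its own threshold computed from its own gray
#' levels (Otsu, or mean plus a multiple of the SD), for the cell on
#' the whole slice and for the clusters on the within-cell voxels
#' only.
#'
#' @param blur_xy Gaussian blur SD in xy voxels.
#' @param blur_z blur SD along z in voxels; the default scales
#'   `blur_xy` by the voxel-size ratio at 3.2/1.0 um so the blur is
#'   roughly isotropic in physical units.
#' @param cell_method,cluster_method threshold rule, `"otsu"` or
#'   `"mean_sd"`.
#' @param cell_scale,cluster_scale multiplier on the computed
#'   threshold.
#' @param cell_c,cluster_c the `c` in mean + c * sd for `"mean_sd"`.
#' @param min_volume minimum cluster component volume in voxels.
#' @param max_clusters keep at most this many largest components.
#' @param cell_floor per-slice cell thresholds are floored at this
#'   fraction of the whole-frame threshold, so slices containing only
#'   blur leakage or noise (outside the cell in z) stay empty while
#'   genuinely attenuated deep slices keep their adaptive threshold.
#' @param max_cluster_frac guard against degenerate slice thresholds:
#'   a slice whose suprathreshold within-cell area exceeds this
#'   fraction carries no cluster signal (an Otsu split of unimodal
#'   cytoplasm noise marks a large area) and contributes nothing.
#' @param gap maximum number of frames a lost cluster is bridged by
#'   holding its last position.
#' @return named list of class `segParams`.
#' @export
segParams <- function(blur_xy = 1, blur_z = blur_xy * 1.0 / 3.2,
                      cell_method = "otsu", cluster_method = "otsu",
                      cell_scale = 1, cluster_scale = 1,
                      cell_c = 2, cluster_c = 3, min_volume = 20,
                      max_clusters = 2, max_cluster_frac = 0.25,
                      cell_floor = 0.3, gap = 2) {
  stopifnot(blur_xy >= 0, blur_z >= 0,
            cell_method %in% c("otsu", "mean_sd"),
            cluster_method %in% c("otsu", "mean_sd"),
            cell_scale > 0, cluster_scale > 0, min_volume >= 0,
            max_clusters >= 1, gap >= 0,
            max_cluster_frac > 0, max_cluster_frac <= 1,
            cell_floor >= 0, cell_floor <= 1)
  p <- list(blur_xy = blur_xy, blur_z = blur_z,
            cell_method = cell_method, cluster_method = cluster_method,
            cell_scale = cell_scale, cluster_scale = cluster_scale,
            cell_c = cell_c, cluster_c = cluster_c,
            min_volume = min_volume, max_clusters = max_clusters,
            max_cluster_frac = max_cluster_frac,
            cell_floor = cell_floor, gap = gap)
  class(p) <- c("segParams", "list")
  p
}

.blur3d <- function(vol, sp) {
  nz <- dim(vol)[1]
  if (sp$blur_xy > 0)
    for (z in seq_len(nz))
      vol[z, , ] <- as.matrix(EBImage::gblur(EBImage::Image(vol[z, , ]),
                                             sigma = sp$blur_xy))
  if (sp$blur_z > 0 && nz >= 3) {
    k <- stats::dnorm(-2:2, sd = max(sp$blur_z, 1e-6))
    k <- k / sum(k)
    out <- vol
    for (z in seq_len(nz)) {
      zi <- pmin(pmax(z + (-2:2), 1), nz)
      acc <- k[1] * vol[zi[1], , ]
      for (j in 2:5) acc <- acc + k[j] * vol[zi[j], , ]
      out[z, , ] <- acc
    }
    vol <- out
  }
  vol
}

.slice_threshold <- function(vals, method, scale, cc) {
  if (length(vals) < 10 || diff(range(vals)) == 0) return(Inf)
  thr <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(matrix(vals, nrow = 1)),
                  range = range(vals))
  } else mean(vals) + cc * stats::sd(vals)
  thr * scale
}

# 3D connected components: per-slice 2D labelling (8-connected)
# merged across adjacent z slices by pixel overlap (union-find)
.label3d <- function(mask) {
  nz <- dim(mask)[1]
  lab <- array(0L, dim = dim(mask))
  offset <- 0L
  for (z in seq_len(nz)) {
    l2 <- EBImage::bwlabel(EBImage::Image(mask[z, , ] * 1))
    l2 <- as.matrix(l2)
    l2[l2 > 0] <- l2[l2 > 0] + offset
    lab[z, , ] <- as.integer(l2)
    offset <- max(offset, max(l2))
  }
  if (offset == 0L) return(lab)
  parent <- seq_len(offset)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (z in seq_len(nz - 1)) {
    a <- lab[z, , ]; b <- lab[z + 1, , ]
    ov <- a > 0 & b > 0
    if (!any(ov)) next
    pairs <- unique(cbind(a[ov], b[ov]))
    for (r in seq_len(nrow(pairs))) {
      ra <- findp(pairs[r, 1]); rb <- findp(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(offset), findp, integer(1))
  relab <- match(roots, unique(roots))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

.centroid_um <- function(idx3, dz, dxy) {
  # idx3: matrix of (z, y, x) 1-based indices
  c(x = mean(idx3[, 3] - 1) * dxy, y = mean(idx3[, 2] - 1) * dxy,
    z = mean(idx3[, 1] - 1) * dz)
}

#' Segment the cell volume of one time point
#'
#' Gaussian blur, per-slice adaptive threshold on the cytoplasmic
#' signal, per-slice hole filling, and selection of the largest 3D
#' connected component.
#'
#' @param frame 3D array (Z, Y, X) of intensities.
#' @param sp a [segParams()] list.
#' @param dz,dxy voxel sizes (um).
#' @return list with `mask` (logical Z,Y,X), `centroid` (um) and
#'   `volume_um3`; errors when no foreground survives thresholding.
#' @export
segmentCell <- function(frame, sp = segParams(), dz = 3.2, dxy = 1.0) {
  stopifnot(length(dim(frame)) == 3)
  if (all(frame == 0)) stop("empty volume: segmentation failed")
  vol <- .blur3d(frame, sp)
  nz <- dim(vol)[1]
  mask <- array(FALSE, dim = dim(vol))
  gcap <- pmin(vol, stats::quantile(vol, 0.9))
  gthr <- .slice_threshold(as.vector(gcap), sp$cell_method,
                           sp$cell_scale, sp$cell_c)
  for (z in seq_len(nz)) {
    pl <- vol[z, , ]
    # cap at the 90th percentile so the small, very bright DNA blobs
    # cannot hijack the cytoplasm/background split
    capped <- pmin(pl, stats::quantile(pl, 0.9))
    thr <- .slice_threshold(as.vector(capped), sp$cell_method,
                            sp$cell_scale, sp$cell_c)
    thr <- max(thr, sp$cell_floor * gthr)
    m <- pl > thr
    if (any(m)) {
      # opening removes speckle noise that would otherwise percolate
      # into components rivalling the cell
      m <- EBImage::opening(EBImage::Image(m * 1),
                            EBImage::makeBrush(3, "box"))
      m <- as.matrix(EBImage::fillHull(m)) > 0
    }
    mask[z, , ] <- m
  }
  if (!any(mask)) stop("empty cell mask: segmentation failed")
  lab <- .label3d(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  idx <- which(mask, arr.ind = TRUE)
  list(mask = mask, centroid = .centroid_um(idx, dz, dxy),
       volume_um3 = sum(mask) * dz * dxy^2)
}

#' Segment DNA clusters of one time point
#'
#' Per-slice adaptive threshold computed on the within-cell voxels of
#' that slice (so deep, attenuated slices get their own, lower
#' threshold), 3D connected components, minimum-volume filter and
#' selection of the largest components. Centroids are
#' intensity-weighted within each component.
#'
#' @param frame 3D array (Z, Y, X).
#' @param cell_mask logical array from [segmentCell()].
#' @param sp a [segParams()] list.
#' @param dz,dxy voxel sizes (um).
#' @return data.frame (x, y, z centroids in um, volume in voxels), 0
#'   rows when no cluster was detected.
#' @export
segmentClusters <- function(frame, cell_mask, sp = segParams(),
                            dz = 3.2, dxy = 1.0) {
  vol <- .blur3d(frame, sp)
  nz <- dim(vol)[1]
  mask <- array(FALSE, dim = dim(vol))
  wvol <- array(0, dim = dim(vol)) # threshold-subtracted weights
  for (z in seq_len(nz)) {
    inside <- cell_mask[z, , ]
    if (!any(inside)) next
    # search slightly beyond the cell outline so blobs apposed to the
    # cortex are not clipped one-sidedly (which would bias centroids
    # inward); threshold statistics still come from within the cell
    search <- as.matrix(EBImage::dilate(
      EBImage::Image(inside * 1), EBImage::makeBrush(9, "disc"))) > 0
    vals <- vol[z, , ][inside]
    thr_cl <- .slice_threshold(vals, sp$cluster_method,
                               sp$cluster_scale, sp$cluster_c)
    capped <- pmin(vol[z, , ], stats::quantile(vol[z, , ], 0.9))
    thr_cell <- .slice_threshold(as.vector(capped), sp$cell_method,
                                 sp$cell_scale, sp$cell_c)
    # the cluster rule must be stricter than the cell rule, and never
    # below a robust bright-outlier floor (median + c * MAD of the
    # within-cell values), which keeps unimodal noise slices empty
    # without being dragged up by the bright blob tail itself
    floor_cl <- stats::median(vals) + sp$cluster_c * stats::mad(vals)
    thr <- max(thr_cl, thr_cell, floor_cl)
    m <- vol[z, , ] > thr & search
    # reject slices where the threshold merely splits cytoplasm noise
    if (sum(m) > sp$max_cluster_frac * sum(inside)) m[] <- FALSE
    if (any(m))
      m <- as.matrix(EBImage::opening(EBImage::Image(m * 1),
                                      EBImage::makeBrush(3, "box"))) > 0
    mask[z, , ] <- m
    wvol[z, , ] <- pmax(vol[z, , ] - thr, 0)
  }
  if (!any(mask))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      volume = numeric(0)))
  lab <- .label3d(mask)
  sizes <- tabulate(lab[lab > 0])
  ids <- which(sizes >= sp$min_volume)
  if (!length(ids))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      volume = numeric(0)))
  ids <- ids[order(sizes[ids], decreasing = TRUE)]
  ids <- utils::head(ids, sp$max_clusters)
  rows <- lapply(ids, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    # centroid from the bright core (above half the component's
    # threshold-subtracted maximum), weighted by that excess: edge
    # voxels, whose extent is biased by the cytoplasm pedestal ending
    # at the cortex, then carry no weight
    w <- wvol[idx]
    core <- w >= 0.5 * max(w)
    idx <- idx[core, , drop = FALSE]; w <- w[core]
    cen <- c(x = sum((idx[, 3] - 1) * w) / sum(w) * dxy,
             y = sum((idx[, 2] - 1) * w) / sum(w) * dxy,
             z = sum((idx[, 1] - 1) * w) / sum(w) * dz)
    data.frame(x = cen["x"], y = cen["y"], z = cen["z"],
               volume = sizes[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster-to-cortex distance (closest-surface-pixel rule)
#'
#' The cell surface is the set of boundary voxels of the mask; the
#' reported distance is the mean 3D Euclidean distance from the
#' cluster centroid to its `q` fraction of closest surface voxels
#' (default 1%), which is robust to local segmentation roughness.
#'
#' @param centroid length-3 (x, y, z) in um.
#' @param cell_mask logical (Z, Y, X) array.
#' @param dz,dxy voxel sizes (um).
#' @param q fraction of closest surface voxels averaged (at least one
#'   voxel is always used).
#' @return distance in um.
#' @export
cortexDistance <- function(centroid, cell_mask, dz = 3.2, dxy = 1.0,
                           q = 0.01) {
  stopifnot(q > 0, q <= 1)
  surf <- .surface_voxels(cell_mask)
  if (!nrow(surf)) stop("empty cell surface")
  d <- sqrt(((surf[, 3] - 1) * dxy - centroid[1])^2 +
              ((surf[, 2] - 1) * dxy - centroid[2])^2 +
              ((surf[, 1] - 1) * dz - centroid[3])^2)
  k <- max(1L, ceiling(q * length(d)))
  mean(sort(d)[seq_len(k)])
}

.surface_voxels <- function(mask) {
  dims <- dim(mask)
  interior <- mask
  shift_and <- function(m, dz_, dy_, dx_) {
    out <- array(FALSE, dim = dims)
    zi <- seq_len(dims[1]) + dz_; yi <- seq_len(dims[2]) + dy_
    xi <- seq_len(dims[3]) + dx_
    okz <- zi >= 1 & zi <= dims[1]; oky <- yi >= 1 & yi <= dims[2]
    okx <- xi >= 1 & xi <= dims[3]
    out[okz, oky, okx] <- m[zi[okz], yi[oky], xi[okx]]
    out
  }
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)))
    interior <- interior & shift_and(mask, s[1], s[2], s[3])
  which(mask & !interior, arr.ind = TRUE)
}

#' Track DNA clusters across frames by proximity
#'
#' Greedy mutual-nearest assignment of per-frame detections to two
#' track slots. A single detection in early frames (metaphase-like)
#' occupies slot 1; a 1 to 2 split starts the second track. Lost
#' detections are bridged for up to `gap` frames by holding the last
#' position (flag `recovered` on reappearance, `lost` beyond the
#' gap). When both assignments are equally plausible (crossing
#' paths), previous labels are kept and the frame is flagged
#' `ambiguous`.
#'
#' @param detections list with one data.frame per frame as returned
#'   by [segmentClusters()].
#' @param times frame times (defaults to 1..T).
#' @param cell_centroids optional T x 3 matrix of cell centroids (um).
#' @param cortex per-frame list of cortex-distance functions or NULL;
#'   see [trackStack()] which fills distances automatically.
#' @param sp a [segParams()] list (for `gap`).
#' @param dz,dxy voxel sizes (um).
#' @return a [ClusterTrack-class].
#' @export
trackClusters <- function(detections, times = NULL,
                          cell_centroids = NULL, cortex = NULL,
                          sp = segParams(), dz = 3.2, dxy = 1.0) {
  nT <- length(detections)
  stopifnot(nT >= 1)
  if (is.null(times)) times <- seq_len(nT)
  pos <- array(NA_real_, dim = c(nT, 2, 3)) # frame, track, xyz
  qc <- character(nT)
  last <- matrix(NA_real_, 2, 3)
  miss <- c(Inf, Inf) # frames since last seen per track

  for (f in seq_len(nT)) {
    det <- detections[[f]]
    flags <- character(0)
    if (!is.null(det) && nrow(det) > 2) {
      det <- det[order(det$volume, decreasing = TRUE)[1:2], ]
      flags <- c(flags, "extra_detections")
    }
    nd <- if (is.null(det)) 0L else nrow(det)
    have <- which(is.finite(last[, 1]))
    if (nd == 0) {
      flags <- c(flags, "no_detection")
      miss <- miss + 1
    } else if (length(have) == 0) {
      for (i in seq_len(nd)) last[i, ] <- unlist(det[i, c("x", "y", "z")])
      miss[seq_len(nd)] <- 0
      if (nd == 1) miss[2] <- Inf
    } else if (length(have) == 1) {
      k <- have
      if (nd == 1) {
        last[k, ] <- unlist(det[1, c("x", "y", "z")])
        miss[k] <- 0
      } else {
        # anaphase split: nearest detection keeps the existing track
        dists <- sqrt(rowSums((t(t(as.matrix(det[, c("x", "y", "z")])) -
                                    last[k, ]))^2))
        i1 <- which.min(dists)
        last[k, ] <- unlist(det[i1, c("x", "y", "z")])
        last[3 - k, ] <- unlist(det[-i1, c("x", "y", "z")][1, ])
        miss[] <- 0
        flags <- c(flags, "split")
      }
    } else {
      if (nd == 1) {
        p <- unlist(det[1, c("x", "y", "z")])
        dists <- sqrt(rowSums((t(t(last) - p))^2))
        k <- which.min(dists)
        last[k, ] <- p
        miss[k] <- 0; miss[3 - k] <- miss[3 - k] + 1
        flags <- c(flags, "merged_or_lost")
      } else {
        P <- as.matrix(det[, c("x", "y", "z")])
        straight <- sqrt(sum((P[1, ] - last[1, ])^2)) +
          sqrt(sum((P[2, ] - last[2, ])^2))
        swapped <- sqrt(sum((P[2, ] - last[1, ])^2)) +
          sqrt(sum((P[1, ] - last[2, ])^2))
        if (abs(straight - swapped) < 1e-9) {
          flags <- c(flags, "ambiguous")
          ord <- 1:2
        } else ord <- if (straight <= swapped) 1:2 else 2:1
        last[1, ] <- P[ord[1], ]; last[2, ] <- P[ord[2], ]
        if (any(miss > 0 & is.finite(miss)))
          flags <- c(flags, "recovered")
        miss[] <- 0
      }
    }
    for (k in 1:2) {
      if (is.finite(last[k, 1]) && miss[k] <= sp$gap)
        pos[f, k, ] <- last[k, ]
      else if (is.finite(last[k, 1]) && miss[k] > sp$gap &&
               is.finite(miss[k]))
        flags <- c(flags, paste0("lost_track", k))
    }
    qc[f] <- paste(unique(flags), collapse = ";")
  }

  cc <- if (is.null(cell_centroids)) matrix(NA_real_, nT, 3) else
    cell_centroids
  fr <- data.frame(frame = seq_len(nT), t = times,
                   c1x = pos[, 1, 1], c1y = pos[, 1, 2],
                   c1z = pos[, 1, 3], c2x = pos[, 2, 1],
                   c2y = pos[, 2, 2], c2z = pos[, 2, 3],
                   cellx = cc[, 1], celly = cc[, 2], cellz = cc[, 3],
                   d1 = NA_real_, d2 = NA_real_, qc = qc)
  new("ClusterTrack", frames = fr, dz = dz, dxy = dxy,
      inIndex = NA_integer_)
}

#' Segment and track a whole stack
#'
#' Runs [segmentCell()], [segmentClusters()] and [trackClusters()]
#' over every time point of an [ImageStack-class], fills in
#' cluster-to-cortex distances (1% closest-surface rule) and assigns
#' in/out labels retrospectively from the final frame (the extruded
#' cluster is the one ending closer to the cortex).
#'
#' @param stack an [ImageStack-class].
#' @param sp a [segParams()] list.
#' @param q closest-surface fraction for [cortexDistance()].
#' @return a [ClusterTrack-class] with distances and `inIndex` set.
#' @export
trackStack <- function(stack, sp = segParams(), q = 0.01) {
  arr <- stackData(stack)
  nT <- dim(arr)[1]
  dz <- stack@dz; dxy <- stack@dxy
  dets <- vector("list", nT)
  cents <- matrix(NA_real_, nT, 3)
  masks <- vector("list", nT)
  for (f in seq_len(nT)) {
    frame <- arr[f, , , , drop = TRUE]
    dim(frame) <- dim(arr)[2:4]
    cell <- segmentCell(frame, sp, dz, dxy)
    cents[f, ] <- cell$centroid
    masks[[f]] <- cell$mask
    dets[[f]] <- segmentClusters(frame, cell$mask, sp, dz, dxy)
  }
  tr <- trackClusters(dets, cell_centroids = cents, sp = sp,
                      dz = dz, dxy = dxy)
  fr <- tr@frames
  for (f in seq_len(nT)) {
    if (is.finite(fr$c1x[f]))
      fr$d1[f] <- cortexDistance(unlist(fr[f, c("c1x", "c1y", "c1z")]),
                                 masks[[f]], dz, dxy, q)
    if (is.finite(fr$c2x[f]))
      fr$d2[f] <- cortexDistance(unlist(fr[f, c("c2x", "c2y", "c2z")]),
                                 masks[[f]], dz, dxy, q)
  }
  lastBoth <- which(is.finite(fr$d1) & is.finite(fr$d2))
  in_idx <- NA_integer_
  if (length(lastBoth)) {
    f <- lastBoth[length(lastBoth)]
    in_idx <- if (fr$d1[f] >= fr$d2[f]) 1L else 2L
  }
  new("ClusterTrack", frames = fr, dz = dz, dxy = dxy,
      inIndex = in_idx)
}
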