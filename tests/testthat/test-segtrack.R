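test_that("cell segmentation recovers the synthetic ball", {
  rp <- renderParams(nx = 80, ny = 80, nz = 20, nt = 1,
                     cell_radius = 25, cluster_peak = 50,
                     cyto_base = 5, noise_sd = 0, seed = 3)
  rs <- renderStack(fixture_static_paths(1), rp)
  f <- stackData(rs$stack)[1, , , ]; dim(f) <- c(20, 80, 80)
  cell <- segmentCell(f)
  true_vol <- 4 / 3 * pi * 25^3
  expect_lt(abs(cell$volume_um3 / true_vol - 1), 0.05)
  expect_lt(max(abs(cell$centroid - rp$cell_center)), 0.5)
  expect_error(segmentCell(array(0, c(4, 10, 10))), "empty")
})

test_that("cluster segmentation finds one or two blobs at SNR 10", {
  rs <- fixture_render(nt = 1, noise_sd = 5, z_decay = 0.05)
  f <- stackData(rs$stack)[1, , , ]; dim(f) <- c(20, 80, 80)
  cell <- segmentCell(f)
  det <- segmentClusters(f, cell$mask)
  expect_equal(nrow(det), 2)
  # detections are volume-ordered; match them to the truth by x
  det <- det[order(det$x), ]
  err1 <- sqrt(sum(((det[1, c("x", "y", "z")] -
                       c(29.5, 54.5, 30.4)) / c(1, 1, 3.2))^2))
  err2 <- sqrt(sum(((det[2, c("x", "y", "z")] -
                       c(49.5, 54.5, 30.4)) / c(1, 1, 3.2))^2))
  expect_lt(err1, 1); expect_lt(err2, 1)
  # a single blob (metaphase-like) is not an error
  rp <- renderParams(nx = 60, ny = 60, nz = 14, nt = 1,
                     cell_radius = 20, cluster_peak = 50,
                     cyto_base = 5, noise_sd = 2, seed = 4)
  p1 <- data.frame(frame = 1, t = 0, c1x = 29.5, c1y = 29.5,
                   c1z = 20.8, c2x = NA, c2y = NA, c2z = NA)
  rs1 <- renderStack(p1, rp)
  f1 <- stackData(rs1$stack)[1, , , ]; dim(f1) <- c(14, 60, 60)
  det1 <- segmentClusters(f1, segmentCell(f1)$mask)
  expect_equal(nrow(det1), 1)
})

test_that("per-slice adaptive thresholds rescue deep attenuated blobs", {
  # strong attenuation: a blob in a deep slice survives the adaptive
  # rule but is missed by one global threshold
  rp <- renderParams(nx = 70, ny = 70, nz = 16, nt = 1,
                     cell_radius = 22, cluster_peak = 40,
                     cyto_base = 5, z_decay = 0.2, noise_sd = 0.5,
                     seed = 6)
  deep_z <- 13 * 3.2 # slice 14, attenuation exp(-0.2*13) ~ 0.07
  pp <- data.frame(frame = 1, t = 0,
                   c1x = 24.5, c1y = 34.5, c1z = 2 * 3.2,
                   c2x = 44.5, c2y = 34.5, c2z = deep_z)
  rs <- renderStack(pp, rp)
  f <- stackData(rs$stack)[1, , , ]; dim(f) <- c(16, 70, 70)
  cell <- segmentCell(f)
  det <- segmentClusters(f, cell$mask)
  expect_equal(nrow(det), 2)
  expect_lt(min(abs(det$z - deep_z)), 3.2)
  # one global cluster threshold (computed on the whole volume) misses
  # the deep blob entirely
  vol <- spinsym:::.blur3d(f, segParams())
  gthr <- spinsym:::.slice_threshold(vol[cell$mask], "otsu", 1, 3)
  deep <- vol[14, , ][cell$mask[14, , ]]
  expect_true(all(deep < gthr))
})

test_that("raising the cluster threshold scale never adds components", {
  rs <- fixture_render(nt = 1, noise_sd = 2)
  f <- stackData(rs$stack)[1, , , ]; dim(f) <- c(20, 80, 80)
  cell <- segmentCell(f)
  counts <- vapply(c(0.8, 1, 1.3, 1.8, 2.5), function(s) {
    nrow(segmentClusters(f, cell$mask,
                         segParams(cluster_scale = s, min_volume = 5)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("tracking keeps identities and bridges dropouts", {
  # two clusters separating linearly over 60 frames
  det <- lapply(1:60, function(f) {
    data.frame(x = c(30 - 0.1 * f, 30 + 0.1 * f),
               y = c(30, 30), z = c(16, 16), volume = c(100, 90))
  })
  tk <- trackClusters(det)
  fr <- trackFrames(tk)
  expect_true(all(diff(fr$c1x) < 0)) # track 1 keeps moving left
  expect_true(all(diff(fr$c2x) > 0))
  # single-frame dropout is bridged and flagged
  det2 <- det[1:10]
  det2[[5]] <- det2[[5]][1, , drop = FALSE]
  tk2 <- trackClusters(det2)
  fr2 <- trackFrames(tk2)
  expect_false(any(is.na(fr2$c2x)))
  expect_match(fr2$qc[6], "recovered")
  # crossing closer than resolution: ambiguity flagged, labels kept
  det3 <- lapply(1:5, function(f) {
    data.frame(x = c(30, 30), y = c(30 - 0.01 * f, 30 + 0.01 * f),
               z = c(16, 16), volume = c(100, 100))
  })
  det3[[3]] <- det3[[3]][c(1, 1), ]
  tk3 <- trackClusters(det3)
  expect_true(any(grepl("ambiguous", trackFrames(tk3)$qc)))
  # 1 -> 2 split starts a second track
  det4 <- c(lapply(1:3, function(f)
    data.frame(x = 30, y = 30, z = 16, volume = 150)),
    lapply(1:3, function(f)
      data.frame(x = c(28, 32), y = c(30, 30), z = c(16, 16),
                 volume = c(80, 80))))
  tk4 <- trackClusters(det4)
  fr4 <- trackFrames(tk4)
  expect_true(all(is.na(fr4$c2x[1:3])))
  expect_true(all(is.finite(fr4$c2x[4:6])))
  expect_match(fr4$qc[4], "split")
})

test_that("cortex distance follows the closest-surface-pixel rule", {
  ball <- fixture_ball_mask(radius_um = 50, pitch = 1)
  d <- cortexDistance(ball$center, ball$mask, dz = 1, dxy = 1, q = 0.01)
  expect_lt(abs(d - 50), 1)
  # q = 1 reduces to the mean over all surface voxels and cannot be
  # smaller than the closest-percentile value
  dall <- cortexDistance(ball$center, ball$mask, dz = 1, dxy = 1, q = 1)
  expect_gte(dall, d)
  # a centroid on the surface of a coarse ball is within a voxel pitch
  small <- fixture_ball_mask(radius_um = 10, pitch = 2)
  edge <- small$center + c(9.5, 0, 0)
  dedge <- cortexDistance(edge, small$mask, dz = 2, dxy = 2, q = 0.01)
  expect_lt(dedge, 2)
})

test_that("distances scale exactly with the voxel-size metadata", {
  # a flat slab with the probe straight above its centre: the nearest
  # surface voxel is the perpendicular foot, so the distance is purely
  # the z component and must double exactly with the z spacing
  slab <- array(FALSE, c(9, 9, 9))
  slab[7, , ] <- TRUE
  probe_idx <- c(4, 4, 2) # (x, y, z) voxel indices, 0-based: 4, 4, 2
  d1 <- cortexDistance(c(4 * 1, 4 * 1, 2 * 3.2), slab,
                       dz = 3.2, dxy = 1, q = 1e-9)
  d2 <- cortexDistance(c(4 * 1, 4 * 1, 2 * 6.4), slab,
                       dz = 6.4, dxy = 1, q = 1e-9)
  expect_equal(d1, 4 * 3.2)
  expect_equal(d2 / d1, 2)
})
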