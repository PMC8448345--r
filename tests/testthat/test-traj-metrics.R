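make_track <- function(c1, c2, cell = NULL, t = NULL) {
  # c1, c2: n x 3 matrices of centroids (um)
  n <- nrow(c1)
  if (is.null(t)) t <- seq_len(n) - 1
  if (is.null(cell)) cell <- matrix(0, n, 3)
  fr <- data.frame(frame = seq_len(n), t = t,
                   c1x = c1[, 1], c1y = c1[, 2], c1z = c1[, 3],
                   c2x = c2[, 1], c2y = c2[, 2], c2z = c2[, 3],
                   cellx = cell[, 1], celly = cell[, 2],
                   cellz = cell[, 3], d1 = NA_real_, d2 = NA_real_,
                   qc = "")
  new("ClusterTrack", frames = fr, dz = 3.2, dxy = 1,
      inIndex = 1L)
}

test_that("cluster distance is the 3D Euclidean distance", {
  tk <- make_track(rbind(c(0, 0, 0), c(0, 0, 0)),
                   rbind(c(3, 4, 0), c(NA, NA, NA)))
  d <- clusterDistance(tk)
  expect_equal(d$d[1], 5)
  expect_true(is.na(d$d[2]))
  # fixed spindle length in simulations
  tr <- simulateSpindle(modelParams(sigma = 1e-3, t_max = 0.5), seed = 2)
  expect_equal(diff(range(clusterDistance(tr)$d)), 0, tolerance = 1e-9)
})

test_that("time registration is the t-axis intercept of the early linear fit", {
  t <- c(10, 20, 30, 40); d <- c(2, 4, 6, 8)
  expect_equal(registerTime(t, d), 0, tolerance = 1e-10)
  # translation equivariance
  expect_equal(registerTime(t + 5, d), 5, tolerance = 1e-10)
  # noisy series with a known onset: d rises from t0 = 12
  set.seed(1)
  tt <- seq(0, 60, by = 2)
  dd <- pmax(0, 0.9 * (tt - 12)) + rnorm(length(tt), 0, 0.3)
  t0 <- registerTime(tt, dd, window = c(14, 30))
  expect_lt(abs(t0 - 12), 2) # within one frame interval
  expect_error(registerTime(c(1, 2, 3), c(3, 2, 1), window = c(1, 3)),
               "slope")
  expect_error(registerTime(c(1, 2), c(1, 2)), "3 points")
})

test_that("rotation angle is measured at the spindle midpoint", {
  # spindle parallel to the cortex: 90 degrees
  tk <- make_track(rbind(c(0.3, 0.8, 0)), rbind(c(-0.3, 0.8, 0)))
  expect_equal(rotationAngle(tk, centroid = c(0, 0, 0))$alpha, 90)
  # fully rotated inward: 0 degrees (in-cluster below the midpoint)
  tk2 <- make_track(rbind(c(0, 0.5, 0)), rbind(c(0, 1.1, 0)))
  expect_equal(rotationAngle(tk2, centroid = c(0, 0, 0))$alpha, 0)
  # undefined when the midpoint sits on the centroid
  tk3 <- make_track(rbind(c(-1, 0, 0)), rbind(c(1, 0, 0)))
  expect_true(is.na(rotationAngle(tk3, centroid = c(0, 0, 0))$alpha))
  # simulated noisy run: alpha falls from 90 and crosses 45 once
  tr <- simulateSpindle(modelParams(sigma = 1e-3), seed = 4)
  al <- rotationAngle(tr)$alpha
  sm <- stats::filter(al, rep(1 / 9, 9), sides = 2)
  crossings <- sum(diff(sign(stats::na.omit(sm) - 45)) != 0)
  expect_equal(crossings, 1)
})

test_that("spin angle is the midpoint displacement seen from the centroid", {
  # midpoints at polar angles 0 and 30 degrees, same radius
  mid_at <- function(ang, r = 0.8)
    c(r * cos(ang * pi / 180), r * sin(ang * pi / 180), 0)
  c1 <- rbind(mid_at(0) + c(0, 0, 0.1), mid_at(30) + c(0, 0, 0.1))
  c2 <- rbind(mid_at(0) - c(0, 0, 0.1), mid_at(30) - c(0, 0, 0.1))
  tk <- make_track(c1, c2)
  expect_equal(spinAngle(tk, centroid = c(0, 0, 0), t_start = 0,
                         t_end = 1), 30, tolerance = 1e-9)
  expect_equal(spinAngle(tk, centroid = c(0, 0, 0), t_start = 0,
                         t_end = 0), 0)
  # a 45-degree arc of midpoints
  angs <- seq(0, 45, length.out = 10)
  c1 <- t(vapply(angs, mid_at, numeric(3)))
  tk2 <- make_track(c1, c1 + rep(c(0, 0, 0.2), each = 10))
  expect_equal(spinAngle(tk2, centroid = c(0, 0, 0), t_start = 0,
                         t_end = 9), 45, tolerance = 0.1)
})

test_that("the five-parameter logistic fit recovers known parameters", {
  t <- seq(1, 60, by = 1)
  truth <- c(A = 90, B = 4, C = 30, D = 5, E = 1.5)
  y <- truth["D"] + (truth["A"] - truth["D"]) /
    (1 + (t / truth["C"])^truth["B"])^truth["E"]
  fit <- fitRotationLogistic(t, y)
  expect_lt(fit@rmse, 1e-6)
  expect_equal(unname(fit@coef[c("A", "D")]),
               unname(truth[c("A", "D")]), tolerance = 1e-3)
  # noisy case: residual RMSE close to the injected noise SD
  set.seed(8)
  yn <- y + rnorm(length(y), 0, 2)
  fitn <- fitRotationLogistic(t, yn)
  expect_gt(fitn@rmse, 1); expect_lt(fitn@rmse, 3)
  # constant series is flagged degenerate
  fd <- fitRotationLogistic(t, rep(45, length(t)))
  expect_true(fd@degenerate)
  expect_warning(expect_true(is.na(rotationOnset(fd))), "degenerate")
})

test_that("rotation onset sits at 5% of the fitted span", {
  # symmetric logistic from 90 to 0 with inflection at t = 30
  t <- seq(1, 60, by = 0.5)
  y <- 90 / (1 + (t / 30)^6)
  fit <- fitRotationLogistic(t, y)
  ti <- rotationOnset(fit)
  expect_lt(ti, 30)
  yi <- fit@coef["D"] + (fit@coef["A"] - fit@coef["D"]) /
    (1 + (ti / fit@coef["C"])^fit@coef["B"])^fit@coef["E"]
  expect_equal(unname(yi), 85.5, tolerance = 0.05)
  # time translation moves the onset with the series (numerically:
  # the 5PL family is not closed under translation, so the refit is
  # equivalent only to fitting accuracy)
  fit2 <- fitRotationLogistic(t + 10, y)
  expect_lt(abs(rotationOnset(fit2) - (ti + 10)) / (ti + 10), 0.01)
  # affine rescaling of the angle axis leaves the onset unchanged
  fit3 <- fitRotationLogistic(t, 2 * y + 15)
  expect_equal(rotationOnset(fit3), ti, tolerance = 1e-3)
})

test_that("cortex distance ratio averages d_in/d_out over the early window", {
  t <- 0:10
  expect_equal(cortexDistanceRatio(t, rep(2, 11), rep(2, 11), c(0, 10)), 1)
  expect_equal(cortexDistanceRatio(t, rep(4, 11), rep(2, 11), c(0, 10)), 2)
  d_out <- rep(2, 11); d_out[3] <- 0
  expect_warning(r <- cortexDistanceRatio(t, rep(4, 11), d_out, c(0, 10)),
                 "excluded")
  expect_equal(r, 2)
})

test_that("onset tertiles are equiprobable with stable tie-breaking", {
  expect_identical(categorizeByOnset(1:9), rep(1:3, each = 3L))
  expect_warning(g <- categorizeByOnset(rep(2, 9)), "equal")
  expect_identical(tabulate(g), rep(3L, 3))
  g70 <- categorizeByOnset(rnorm(70))
  expect_lte(diff(range(tabulate(g70))), 1L)
  expect_error(categorizeByOnset(c(1, 2)), "at least 3")
})

test_that("relocation speed is the windowed slope with a 20 um class cut", {
  t <- seq(0, 60, by = 2)
  rs <- relocationSpeed(t, rep(35, length(t)))
  expect_equal(rs$slope, 0)
  expect_identical(rs$class, "peripheral")
  d <- 35 - 0.5 * pmax(0, pmin(t, 50) - 10)
  rs2 <- relocationSpeed(t, d)
  expect_equal(rs2$slope, -0.5, tolerance = 1e-9)
  expect_identical(rs2$class, "relocated")
  # injected drift recovered within 5% under noise
  set.seed(3)
  dn <- 40 - 0.4 * t + rnorm(length(t), 0, 0.2)
  expect_equal(relocationSpeed(t, dn)$slope, -0.4, tolerance = 0.05 * 0.4)
})

test_that("metrics agree between a trajectory and its rendered track", {
  # high SNR, fine sampling: the imaging pipeline must reproduce the
  # simulation-side distance and angle up to rendering resolution
  p <- modelParams(sigma = 1e-3)
  tr <- simulateSpindle(p, seed = 6)
  rp <- renderParams(nx = 80, ny = 80, nz = 20, nt = 8,
                     cell_radius = 25, cluster_peak = 60,
                     cyto_base = 6, noise_sd = 0.5, seed = 9)
  rs <- renderStack(tr, rp)
  tk <- trackStack(rs$stack)
  d_img <- clusterDistance(tk)$d
  d_true <- p$L0 * rp$cell_radius
  expect_true(all(abs(d_img - d_true) / d_true < 0.02))
  idx <- round(seq(1, nrow(trajFrames(tr)), length.out = rp$nt))
  a_true <- trajFrames(tr)$alpha[idx]
  a_img <- rotationAngle(tk, centroid = rp$cell_center)$alpha
  expect_true(all(abs(a_img - a_true) < 2))
})
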