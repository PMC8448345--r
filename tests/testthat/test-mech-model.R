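test_that("potential has its minimum at r_a and the documented well depth", {
  p <- default_params()
  # closed form at the minimum: V(r_a) = -A * lam * exp(-r_a/lam)
  expect_equal(potentialV(p$r_a, p), -p$A * p$lam * exp(-p$r_a / p$lam),
               tolerance = 1e-12)
  expect_equal(potentialV(p$r_a, p), -3.953957, tolerance = 1e-6)
  # the factor (r - r_a + lam) vanishes at r_a - lam
  expect_equal(potentialV(p$r_a - p$lam, p), 0)
  # stationary point at r_a by central differences
  h <- 1e-6
  dV <- (potentialV(p$r_a + h, p) - potentialV(p$r_a - h, p)) / (2 * h)
  expect_lt(abs(dV), 1e-6)
  # unique minimum on a grid, decay at long range
  r <- seq(0.001, 1.5, by = 1e-3)
  expect_lt(abs(r[which.min(potentialV(r, p))] - p$r_a), 1e-3)
  expect_lt(abs(potentialV(p$r_a + 10 * p$lam, p)),
            1e-2 * abs(potentialV(p$r_a, p)))
  # soft repulsive core
  expect_true(all(potentialV(seq(0, p$r_a - p$lam - 1e-3, by = 1e-3), p) > 0))
  expect_error(potentialV(-0.1, p), "non-negative")
})

test_that("attraction force matches the numerical gradient of the potential", {
  p <- default_params()
  anchor <- c(0, 1)
  h <- 1e-7
  for (r in seq(0.01, 1, length.out = 50)) {
    f <- attractionForce(c(0, 1 - r), anchor, p)
    # with u_r = (0, -1) the force -dV/dr * u_r has y-component +dV/dr
    num <- (potentialV(r + h, p) - potentialV(r - h, p)) / (2 * h)
    expect_equal(f[2], num, tolerance = 1e-6 * max(1, abs(num)))
    expect_equal(f[1], 0)
  }
  # documented magnitude at r = 0.3
  f <- attractionForce(c(0, 0.7), anchor, p)
  expect_equal(sqrt(sum(f^2)), 12.44677, tolerance = 1e-4)
  expect_gt(f[2], 0) # toward the anchor
  # zero at the well minimum
  expect_equal(attractionForce(c(0, 1 - p$r_a), anchor, p), c(0, 0),
               tolerance = 1e-12)
  # monotone decay beyond r_a + lam
  rs <- seq(p$r_a + p$lam, 1, length.out = 40)
  mags <- vapply(rs, function(r)
    sqrt(sum(attractionForce(c(0, 1 - r), anchor, p)^2)), numeric(1))
  expect_true(all(diff(mags) < 0))
  expect_warning(attractionForce(anchor, anchor, p), "zero")
})

test_that("elastic force is k times the perpendicular deflection", {
  p <- default_params()
  st <- list(x1 = c(-0.4, 0.8), x2 = c(0.4, 0.8), c = c(0, 0.7))
  ef <- elasticForce(st, p)
  expect_equal(ef$w, c(0, -0.1), tolerance = 1e-12)
  expect_equal(ef$force, c(0, -20), tolerance = 1e-12)
  # midpoint coincident with c: zero
  st$c <- c(0, 0.8)
  expect_equal(elasticForce(st, p)$force, c(0, 0))
  # offset purely along the chord: zero
  st$c <- c(0.25, 0.8)
  expect_equal(elasticForce(st, p)$force, c(0, 0), tolerance = 1e-12)
  st$x2 <- st$x1
  expect_error(elasticForce(st, p), "coincident")
})

test_that("initial configuration places both clusters in their wells", {
  p <- default_params()
  st <- initState(p)
  r1 <- sqrt(sum((st$x1 - st$a1)^2))
  r2 <- sqrt(sum((st$x2 - st$a2)^2))
  expect_equal(r1, p$r_a, tolerance = 1e-12)
  expect_equal(r2, p$r_a, tolerance = 1e-12)
  expect_equal(r1 - r2, 0)
  expect_equal(sqrt(sum((st$x2 - st$x1)^2)), p$L0, tolerance = 1e-12)
  expect_equal(sqrt(sum(st$a1^2)), p$R_ovo)
  expect_equal(elasticForce(st, p)$force, c(0, 0))
  expect_error(initState(modelParams(L0 = 1.9)), "L0")
})

test_that("a zero-force, zero-noise step is the Euler identity", {
  # flat potential (A = 0), c at midpoint, sigma = 0
  p <- modelParams(A = 1e-300, sigma = 0, dt = 1e-3)
  st <- initState(p)
  st2 <- stepState(st, p)
  expect_equal(st2$x1, st$x1, tolerance = 1e-9)
  expect_equal(st2$x2, st$x2, tolerance = 1e-9)
  expect_equal(st2$c, st$c + p$u_cyto * p$dt * st$dir, tolerance = 1e-12)
  expect_equal(st2$t, p$dt)
})

test_that("a single off-well cluster relaxes like the 1D overdamped ODE", {
  skip_if_not_installed("deSolve")
  p <- modelParams(sigma = 0, k = 0, u_cyto = 0, dt = 1e-4)
  # place both clusters off their wells symmetrically; with k = 0 and
  # no ingression each follows the pure 1D radial dynamics
  st <- initState(p)
  push <- 0.1
  st$x1 <- st$x1 * (1 - push); st$x2 <- st$x2 * (1 - push)
  st$c <- (st$x1 + st$x2) / 2
  r0 <- sqrt(sum((st$x1 - st$a1)^2))
  rhs <- function(t, y, parms) {
    dV <- -p$A * exp(-y / p$lam) * (p$r_a - y) / p$lam
    list(-dV / p$damping)
  }
  times <- seq(0, 0.05, by = 0.005)
  ode <- deSolve::ode(y = r0, times = times, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  cur <- st
  for (i in seq_len(0.05 / p$dt)) cur <- stepState(cur, p)
  r_end <- sqrt(sum((cur$x1 - st$a1)^2))
  expect_equal(r_end, unname(ode[nrow(ode), 2]), tolerance = 1e-3)
  # relaxation is monotone toward r_a
  expect_lt(abs(r_end - p$r_a), abs(r0 - p$r_a))
})

test_that("noiseless simulation stays perfectly mirror-symmetric", {
  tr <- simulateSpindle(modelParams(sigma = 0), seed = 1)
  expect_identical(trajOutcome(tr), "symmetric")
  expect_lt(tr@maxAsym, 1e-10)
  fr <- trajFrames(tr)
  expect_true(all(abs(fr$r1 - fr$r2) < 1e-10))
  expect_true(all(abs(fr$alpha - 90) < 1e-6))
})

test_that("chord length is conserved and clusters stay inside the oocyte", {
  p <- modelParams(sigma = 1e-2)
  tr <- simulateSpindle(p, seed = 7, thin = 1L)
  fr <- trajFrames(tr)
  chord <- sqrt((fr$x2x - fr$x1x)^2 + (fr$x2y - fr$x1y)^2)
  expect_true(all(abs(chord - p$L0) < 1e-9))
  expect_true(all(fr$x1x^2 + fr$x1y^2 <= p$R_ovo^2 + 1e-12))
  expect_true(all(fr$x2x^2 + fr$x2y^2 <= p$R_ovo^2 + 1e-12))
})

test_that("identical seeds give bitwise-identical trajectories", {
  p <- modelParams(sigma = 1e-3)
  a <- simulateSpindle(p, seed = 42)
  b <- simulateSpindle(p, seed = 42)
  expect_identical(trajFrames(a), trajFrames(b))
  c <- simulateSpindle(p, seed = 43)
  expect_false(identical(trajFrames(a), trajFrames(c)))
})

test_that("halving dt changes the noiseless endpoint at first order", {
  ends <- vapply(c(4e-3, 2e-3, 1e-3, 5e-4), function(dt) {
    tr <- simulateSpindle(modelParams(sigma = 0, dt = dt, t_max = 0.4),
                          seed = 1, early_stop = FALSE)
    fr <- trajFrames(tr)
    fr$r1[nrow(fr)]
  }, numeric(1))
  d1 <- abs(ends[1] - ends[2]); d2 <- abs(ends[2] - ends[3])
  d3 <- abs(ends[3] - ends[4])
  # successive halvings shrink the change by about 2 (first order)
  expect_gt(d1 / d2, 1.5); expect_lt(d1 / d2, 3)
  expect_gt(d2 / d3, 1.5); expect_lt(d2 / d3, 3)
})

test_that("small noise breaks the symmetry and the ensemble is reproducible", {
  p <- modelParams(sigma = 1e-3)
  es <- runEnsemble(p, n = 10, seed = 3, fit_onset = FALSE)
  expect_true(all(es$outcome == "broken"))
  es2 <- runEnsemble(p, n = 10, seed = 3, fit_onset = FALSE)
  expect_identical(es, es2)
  expect_true(all(es$in_index %in% 1:2))
  # both rotation directions occur
  es3 <- suppressWarnings(
    runEnsemble(modelParams(sigma = 1e-2), n = 30, seed = 5,
                fit_onset = FALSE))
  expect_gt(length(unique(es3$in_index)), 1)
})
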