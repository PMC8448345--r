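# shared fixtures, all generated in code

default_params <- function(...) modelParams(...)

# two static blobs 20 um apart in a 25 um cell, 3 frames
fixture_static_paths <- function(nt = 3) {
  data.frame(frame = seq_len(nt), t = seq_len(nt) - 1,
             c1x = 29.5, c1y = 54.5, c1z = 30.4,
             c2x = 49.5, c2y = 54.5, c2z = 30.4)
}

fixture_render <- function(nt = 3, noise_sd = 1, z_decay = 0.05,
                           seed = 2) {
  rp <- renderParams(nx = 80, ny = 80, nz = 20, nt = nt,
                     cell_radius = 25, cluster_peak = 50,
                     cyto_base = 5, z_decay = z_decay,
                     noise_sd = noise_sd, seed = seed)
  renderStack(fixture_static_paths(nt), rp)
}

# digital ball mask for cortex-distance geometry checks
fixture_ball_mask <- function(radius_um = 50, pitch = 1) {
  n <- 2 * ceiling(radius_um / pitch) + 5
  cs <- (n - 1) / 2 * pitch
  xs <- (seq_len(n) - 1) * pitch
  d2 <- outer((xs - cs)^2, (xs - cs)^2, "+")
  m <- array(FALSE, c(n, n, n))
  for (z in seq_len(n)) m[z, , ] <- d2 + (xs[z] - cs)^2 <= radius_um^2
  list(mask = m, center = c(cs, cs, cs), pitch = pitch)
}
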