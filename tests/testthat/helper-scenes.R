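# shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small, fast 1D test system (not the reference calibration)
toy_params <- function(tau = 3600)
  model_params_1d(E = 1000, eta = 1000 * tau, gamma = 1.5e4, kM = 30,
                  dsigma = 1530, L = 60)

toy_protocol <- function() activation_protocol(25, 35, 900, 1800, 180, 30)

toy_grid <- function(n_nodes = 61, dt_step = 2, t_end = 2700)
  sim_grid(n_nodes = n_nodes, L = 60, dt_output = 20, t_end = t_end,
           dt_step = dt_step)

r1_trajectory <- function()
  fixture("r1_traj", function()
    simulate_1d(reference_params("R1"), reference_protocol(),
                reference_grid()))

r2_trajectory <- function()
  fixture("r2_traj", function()
    simulate_1d(reference_params("R2"), reference_protocol(),
                reference_grid()))

# small noiseless fibre scene for image-chain tests (short cell, coarse px)
small_fibre_scene <- function(noise = FALSE, seed = 42) {
  fixture(paste0("fibre_scene_", noise, "_", seed), function() {
    p <- model_params_1d(E = 1000, eta = 3.6e6, gamma = 1.5e4, kM = 30,
                         dsigma = 1530, L = 30)
    pr <- activation_protocol(12, 18, 900, 1800, 180, 30)
    gen_fibre_movie(p, pr, seed = seed, pixel_size = 0.108, height_px = 32,
                    noise = noise,
                    grid = sim_grid(61, 30, 20, 2700, 1))
  })
}

# textured test image with reproducible content
textured_image <- function(n = 96, seed = 3, sigma = 2) {
  set.seed(seed)
  EBImage::gblur(matrix(runif(n * n), n, n), sigma)
}

# render a bead image directly (bypasses gen_bead_scene)
render_beads <- function(bx, by, amp, n, pixel_size, sigma = 1.3) {
  img <- matrix(0, n, n)
  half <- ceiling(4 * sigma)
  cpx <- bx / pixel_size + 0.5; cpy <- by / pixel_size + 0.5
  for (b in seq_along(cpx)) {
    c0 <- round(cpx[b]); r0 <- round(cpy[b])
    rc <- max(1, c0 - half):min(n, c0 + half)
    rr <- max(1, r0 - half):min(n, r0 + half)
    img[rr, rc] <- img[rr, rc] + amp[b] *
      exp(-(outer((rr - cpy[b])^2, (rc - cpx[b])^2, "+")) / (2 * sigma^2))
  }
  img
}

# sample a truth field stored on the pixel grid at physical coordinates
sample_field <- function(M, qx, qy, pixel_size) {
  matrix(fibremech:::bilinear_at(
    M, outer(qy / pixel_size + 0.5, rep(1, length(qx))),
    outer(rep(1, length(qy)), qx / pixel_size + 0.5)), length(qy))
}
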