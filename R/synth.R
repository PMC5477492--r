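#' Synthetic fibre movie with complete ground truth
#'
#' Renders a punctate stress-fibre movie emulating confocal acquisition:
#' Gaussian puncta seeded along a horizontal fibre are advected by the 1D
#' continuum model's displacement field plus a constant baseline retrograde
#' drift toward the activation-region centre; intensity inside the
#' activation region rises by the accumulation factor `1 + a f(t)`; the
#' whole frame bleaches as `exp(-t / tau_b)`; Poisson shot noise and
#' Gaussian read noise are added; frames are quantized to 16-bit counts.
#'
#' @param params a [model_params_1d()].
#' @param protocol an [activation_protocol()].
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @param pixel_size um per px (default 0.108).
#' @param height_px frame height (the fibre runs horizontally mid-frame).
#' @param dt frame interval (s), default 20.
#' @param t_end movie end (s), default 2700 (15/15/15 min phases).
#' @param puncta_spacing mean spacing of puncta along the fibre (um).
#' @param accumulation fold-increase amplitude `a` of intensity in the
#'   activation region (default 0.5, i.e. 1.5-fold at plateau).
#' @param drift baseline retrograde speed `v0` (um/s, default 0.001 =
#'   1 nm/s), directed toward the activation-region centre on both flanks.
#' @param bleach_tau bleaching time constant (s), default 2400.
#' @param peak_photons photon count at a punctum peak (sets shot noise;
#'   default 400, puncta SNR ~ 10 over background).
#' @param read_noise Gaussian read noise (counts), default 2.
#' @param background background photon level (counts), default 40.
#' @param noise logical; disable to render noiseless frames.
#' @param grid simulation grid override.
#' @return object of class `"synthetic_scene"`: `stack` (frames x H x W,
#'   counts), `pixel_size`, `dt`, `phases`, and `truth` (model trajectory,
#'   puncta tracks in um and px, per-frame fibre displacement field, fibre
#'   row, activation region in px and um, all generator settings).
#' @export
gen_fibre_movie <- function(params, protocol, seed = 1,
                            pixel_size = 0.108, height_px = 48, dt = 20,
                            t_end = 2700, puncta_spacing = 1,
                            accumulation = 0.5, drift = 0.001,
                            bleach_tau = 2400, peak_photons = 400,
                            read_noise = 2, background = 40, noise = TRUE,
                            grid = NULL) {
  set.seed(seed)
  if (is.null(grid))
    grid <- sim_grid(n_nodes = 121, L = params$L, dt_output = dt,
                     t_end = t_end, dt_step = 1)
  traj <- simulate_1d(params, protocol, grid)
  times <- traj$times
  nf <- length(times)
  margin_px <- 12
  W <- as.integer(ceiling(params$L / pixel_size)) + 2L * margin_px
  H <- as.integer(height_px)
  fibre_row <- (H + 1) / 2
  centre <- (protocol$a + protocol$b) / 2

  # puncta positions (um along the cell axis), jittered regular spacing
  x0 <- seq(puncta_spacing / 2, params$L - puncta_spacing / 2,
            by = puncta_spacing)
  x0 <- x0 + runif(length(x0), -0.25, 0.25) * puncta_spacing
  x0 <- pmin(pmax(x0, 0), params$L)
  amp <- runif(length(x0), 0.7, 1.3)

  # material displacement of each punctum: model field + constant drift
  u_of <- function(xq, ti) approx(traj$x, traj$u[, ti], xout = xq,
                                  rule = 2)$y
  drift_dir <- -sign(x0 - centre)        # toward the activation centre
  pos_um <- matrix(NA_real_, length(x0), nf)
  for (ti in seq_len(nf))
    pos_um[, ti] <- x0 + u_of(x0, ti) + drift * drift_dir * times[ti]

  sigma_px <- 0.3 / pixel_size
  col_of <- function(xum) xum / pixel_size + margin_px + 0.5
  ramp <- activation_ramp(times, protocol)
  bleach <- exp(-times / bleach_tau)

  stack <- array(0, c(nf, H, W))
  half <- ceiling(4 * sigma_px)
  prof_r <- exp(-((seq_len(H) - fibre_row)^2) / (2 * sigma_px^2))
  for (ti in seq_len(nf)) {
    frame <- matrix(0, H, W)
    cols <- col_of(pos_um[, ti])
    inside <- pos_um[, ti] >= protocol$a & pos_um[, ti] <= protocol$b
    gain <- amp * (1 + accumulation * ramp[ti] * inside)
    for (p in seq_along(cols)) {
      c0 <- round(cols[p])
      rng <- max(1, c0 - half):min(W, c0 + half)
      prof_c <- exp(-((rng - cols[p])^2) / (2 * sigma_px^2))
      frame[, rng] <- frame[, rng] + gain[p] * outer(prof_r, prof_c)
    }
    expected <- (background + peak_photons * frame) * bleach[ti]
    if (noise) {
      counts <- rpois(length(expected), lambda = expected) +
        rnorm(length(expected), sd = read_noise)
      frame <- matrix(pmax(0, round(counts)), H, W)
    } else frame <- expected
    stack[ti, , ] <- frame
  }
  structure(list(
    stack = stack, pixel_size = pixel_size, dt = dt,
    phases = c(baseline = protocol$t_on, activation = protocol$t_off,
               end = t_end),
    truth = list(params = params, protocol = protocol, grid = grid,
                 trajectory = traj, puncta_x0 = x0, puncta_um = pos_um,
                 puncta_col = col_of(pos_um), fibre_row = fibre_row,
                 margin_px = margin_px, drift = drift,
                 accumulation = accumulation, bleach_tau = bleach_tau,
                 seed = seed)),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %d frames of %d x %d px, %g um/px, dt %g s\n",
              dim(x$stack)[1], dim(x$stack)[2], dim(x$stack)[3],
              x$pixel_size, x$dt))
  invisible(x)
}

#' Synthetic bead-image pair deformed by known tractions
#'
#' Builds a traction field as a sum of contractile Gaussian force dipoles
#' (net force zero by construction), computes the substrate surface
#' displacement with the forward Boussinesq operator, renders a random bead
#' field, and warps it by the displacement.
#'
#' @param n_px image side (px); the traction/displacement grids share it.
#' @param pixel_size um per px (default 0.215, a 2x-binned bead channel).
#' @param substrate a [substrate_props()].
#' @param dipoles data.frame (`x`, `y` centre um, `ux`, `uy` unit axis,
#'   `sep` um, `amp` Pa, `sigma` um); `NULL` gives a default pattern of 4
#'   dipoles.
#' @param bead_density beads per um^2 (default 1.2).
#' @param bead_sigma bead spot sigma (px).
#' @param amplitude_scale per-frame multipliers of the traction amplitude
#'   (default 1: a single deformed frame).
#' @param peak_photons,read_noise,background,noise noise model as in
#'   [gen_fibre_movie()].
#' @param seed integer seed.
#' @return object of class `"bead_scene"`: `reference` (H x W), `deformed`
#'   (frames x H x W), `pixel_size`, and `truth` (traction and displacement
#'   [vector_field_2d()]s per frame, bead positions, strain energies).
#' @export
gen_bead_scene <- function(n_px = 256, pixel_size = 0.215,
                           substrate = substrate_props(), dipoles = NULL,
                           bead_density = 2.5, bead_sigma = 1.3,
                           amplitude_scale = 1, peak_photons = 300,
                           read_noise = 2, background = 20, noise = TRUE,
                           seed = 1) {
  set.seed(seed)
  fov <- n_px * pixel_size
  if (is.null(dipoles)) {
    ctr <- fov / 2
    r <- fov * 0.28
    ang <- c(0, pi / 2, pi, 3 * pi / 2) + pi / 7
    # four cell-scale contractile dipoles pulling toward the centre;
    # feature scale well above the PIV window so the measurement chain is
    # operated in its resolved regime
    dipoles <- data.frame(x = ctr + r * cos(ang), y = ctr + r * sin(ang),
                          ux = -cos(ang), uy = -sin(ang),
                          sep = 16, amp = 1500, sigma = 5)
  }
  xs <- (seq_len(n_px) - 0.5) * pixel_size
  gx <- matrix(xs, n_px, n_px, byrow = TRUE)
  gy <- matrix(xs, n_px, n_px)
  tx <- matrix(0, n_px, n_px); ty <- matrix(0, n_px, n_px)
  for (i in seq_len(nrow(dipoles))) {
    d <- dipoles[i, ]
    for (s in c(-1, 1)) {
      cx <- d$x + s * d$ux * d$sep / 2
      cy <- d$y + s * d$uy * d$sep / 2
      blob <- exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * d$sigma^2))
      # the two poles pull toward each other (contractile dipole)
      tx <- tx - s * d$ux * d$amp * blob
      ty <- ty - s * d$uy * d$amp * blob
    }
  }
  tx <- tx - mean(tx); ty <- ty - mean(ty)   # exact zero net force
  T1 <- vector_field_2d(tx, ty, pixel_size, "traction")

  n_beads <- rpois(1, bead_density * fov^2)
  bx <- runif(n_beads, 1, fov - 1)
  by <- runif(n_beads, 1, fov - 1)
  bamp <- runif(n_beads, 0.6, 1.4)

  render <- function(px, py) {
    img <- matrix(0, n_px, n_px)
    half <- ceiling(4 * bead_sigma)
    cpx <- px / pixel_size + 0.5; cpy <- py / pixel_size + 0.5
    for (b in seq_along(cpx)) {
      c0 <- round(cpx[b]); r0 <- round(cpy[b])
      rc <- max(1, c0 - half):min(n_px, c0 + half)
      rr <- max(1, r0 - half):min(n_px, r0 + half)
      img[rr, rc] <- img[rr, rc] + bamp[b] *
        exp(-(outer((rr - cpy[b])^2, (rc - cpx[b])^2, "+")) /
              (2 * bead_sigma^2))
    }
    img
  }
  add_noise <- function(img) {
    expected <- background + peak_photons * img
    if (!noise) return(expected)
    matrix(pmax(0, round(rpois(length(expected), expected) +
                           rnorm(length(expected), sd = read_noise))),
           n_px, n_px)
  }
  reference <- add_noise(render(bx, by))
  truth <- list(traction = list(), displacement = list(),
                beads = cbind(x = bx, y = by), strain_energy = numeric(0),
                substrate = substrate, dipoles = dipoles, seed = seed)
  deformed <- array(0, c(length(amplitude_scale), n_px, n_px))
  for (f in seq_along(amplitude_scale)) {
    Tf <- vector_field_2d(tx * amplitude_scale[f], ty * amplitude_scale[f],
                          pixel_size, "traction")
    uf <- greens_forward(Tf, substrate)
    ub_x <- bilinear_at(uf$vx, by / pixel_size + 0.5, bx / pixel_size + 0.5)
    ub_y <- bilinear_at(uf$vy, by / pixel_size + 0.5, bx / pixel_size + 0.5)
    deformed[f, , ] <- add_noise(render(bx + ub_x, by + ub_y))
    truth$traction[[f]] <- Tf
    truth$displacement[[f]] <- uf
    truth$strain_energy[f] <- strain_energy_2d(Tf, uf)
  }
  structure(list(reference = reference, deformed = deformed,
                 pixel_size = pixel_size, truth = truth),
            class = "bead_scene")
}

#' Synthetic focal-adhesion movie
#'
#' Elliptical Gaussian adhesions with programmed intensity (and optional
#' stress) time profiles over a baseline/activation/relaxation protocol.
#'
#' @param n_adhesions number of adhesions.
#' @param risers indices of adhesions whose intensity rises during
#'   activation.
#' @param rise_factor peak intensity multiple during activation for risers
#'   (default 1.3).
#' @param n_px frame side (px).
#' @param pixel_size um per px.
#' @param dt frame interval (s); `t_end` movie end (s).
#' @param t_on,t_off activation window (s).
#' @param noise,peak_photons,read_noise,background noise model.
#' @param seed integer seed; adhesion placements with excessive overlap are
#'   re-drawn.
#' @return object of class `"synthetic_scene"` with `truth` listing the
#'   adhesion centres, axes, and which exceed the 10% rise rule.
#' @export
gen_adhesion_movie <- function(n_adhesions = 10, risers = integer(0),
                               rise_factor = 1.3, n_px = 192,
                               pixel_size = 0.108, dt = 60, t_end = 2700,
                               t_on = 900, t_off = 1800, noise = TRUE,
                               peak_photons = 500, read_noise = 2,
                               background = 20, seed = 1) {
  set.seed(seed)
  min_sep <- 34                      # keeps thresholded blobs disjoint
  cx <- numeric(0); cy <- numeric(0)
  for (i in seq_len(n_adhesions)) {
    for (attempt in 1:500) {
      px <- runif(1, 15, n_px - 15); py <- runif(1, 15, n_px - 15)
      if (!length(cx) || min(sqrt((cx - px)^2 + (cy - py)^2)) > min_sep)
        break
      if (attempt == 500)
        stop("could not place ", n_adhesions,
             " non-overlapping adhesions; reduce the count", call. = FALSE)
    }
    cx <- c(cx, px); cy <- c(cy, py)
  }
  ax <- runif(n_adhesions, 3, 6)       # semi-axes, px
  ay <- runif(n_adhesions, 1.5, 3)
  th <- runif(n_adhesions, 0, pi)
  times <- seq(0, t_end, by = dt)
  nf <- length(times)
  ramp <- pmin(1, pmax(0, (times - t_on) / 120)) *
    (times < t_off) + (times >= t_off) * pmax(0, 1 - (times - t_off) / 120)
  profiles <- matrix(1, n_adhesions, nf)
  for (i in risers) profiles[i, ] <- 1 + (rise_factor - 1) * ramp
  stack <- array(0, c(nf, n_px, n_px))
  base <- list()
  for (i in seq_len(n_adhesions)) {
    xr <- (col(matrix(0, n_px, n_px)) - cx[i])
    yr <- (row(matrix(0, n_px, n_px)) - cy[i])
    xp <- xr * cos(th[i]) + yr * sin(th[i])
    yp <- -xr * sin(th[i]) + yr * cos(th[i])
    base[[i]] <- exp(-(xp^2 / (2 * ax[i]^2) + yp^2 / (2 * ay[i]^2)))
  }
  for (f in seq_len(nf)) {
    img <- Reduce(`+`, Map(function(b, s) b * s, base, profiles[, f]))
    expected <- background + peak_photons * img
    stack[f, , ] <- if (noise)
      matrix(pmax(0, round(rpois(length(expected), expected) +
                             rnorm(length(expected), sd = read_noise))),
             n_px, n_px)
    else expected
  }
  structure(list(stack = stack, pixel_size = pixel_size, dt = dt,
                 phases = c(baseline = t_on, activation = t_off,
                            end = t_end),
                 truth = list(centres = cbind(x = cx, y = cy),
                              axes = cbind(ax, ay), theta = th,
                              profiles = profiles, risers = risers,
                              exceeds_10pct = seq_len(n_adhesions) %in%
                                risers & rise_factor > 1.10,
                              times = times, seed = seed)),
            class = "synthetic_scene")
}

#' Reference synthetic scenes R1 (elastic-like) and R2 (fluid-like)
#'
#' The two frozen study scenes: identical acquisition (45 min at 20 s, a
#' 10 um activation region, 1 nm/s baseline drift) and identical parameters
#' except the relaxation time: R1 uses `eta/E` = 60 min (elastic recoil),
#' R2 uses 1 s (no recoil).
#'
#' @param seed integer seed (shared by both scenes).
#' @param which subset of scenes to build.
#' @param ... passed to [gen_fibre_movie()].
#' @return named list of [gen_fibre_movie()] scenes.
#' @export
reference_scenes <- function(seed = 20, which = c("R1", "R2"), ...) {
  pr <- reference_protocol()
  out <- lapply(which, function(s)
    gen_fibre_movie(reference_params(s), pr, seed = seed, ...))
  names(out) <- which
  out
}

#' Flank flow summary of a signed-speed kymograph
#'
#' Averages projected flow in windows adjacent to the activation region,
#' re-signed so that positive means "toward the activation region", and
#' reports per-phase summaries: mean per-pixel speed magnitude in the
#' baseline phase, mean toward-region speed during activation, and mean
#' away-from-region speed during relaxation.
#'
#' @param kymo a signed-speed [kymograph()] (um/s).
#' @param activation_region arc interval (um, length 2).
#' @param t_on,t_off activation switch times (s).
#' @param window flank window width (um), default 5.
#' @return named numeric vector (`pre_mag`, `act_toward`, `rel_away`) in
#'   nm/s.
#' @export
flank_flow_summary <- function(kymo, activation_region, t_on = 900,
                               t_off = 1800, window = 5) {
  xs <- kymo_space(kymo)
  ts <- kymo_time(kymo)
  left <- xs >= activation_region[1] - window & xs < activation_region[1]
  right <- xs > activation_region[2] & xs <= activation_region[2] + window
  pre <- ts < t_on
  act <- ts >= t_on & ts < t_off
  rel <- ts >= t_off
  V <- kymo$values
  toward <- rbind(V[left, , drop = FALSE], -V[right, , drop = FALSE])
  c(pre_mag = mean(abs(toward[, pre])) * 1000,
    act_toward = mean(toward[, act]) * 1000,
    rel_away = -mean(toward[, rel]) * 1000)
}
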