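#' Simulate the 1D active Maxwell cell
#'
#' Integrates the continuum model of a contractile cell: a continuum of
#' contractile elements in series, each in parallel with an elastic and a
#' viscous element in series (an "active Maxwell fluid"), frictionally
#' coupled to an elastic substrate. Local activation adds contractile stress
#' inside the protocol's region with an exponentially plateauing ramp.
#'
#' The governing equations are: passive stress dynamics
#' `d(sigma_p)/dt = E dv/dx - (E/eta) sigma_p`; total stress
#' `sigma = sigma_p + sigma_a(x, t)`; quasi-static force balance
#' `d(sigma)/dx = kM w`; and substrate friction `dw/dt = v - (kM/gamma) w`,
#' where `w` is the substrate displacement and traction is `kM w`.
#' The default boundary condition is stress-free ends (`sigma = 0`);
#' `boundary = "clamped"` pins the end velocities instead.
#'
#' Integration uses a method-of-lines scheme with a tridiagonal quasi-static
#' velocity solve at every step and an exponential (exact-relaxation) update
#' of the passive stress, which remains stable even when the relaxation time
#' `eta/E` is far below the step size.
#'
#' @param params a [model_params_1d()].
#' @param protocol an [activation_protocol()]; its region must lie in
#'   `[0, L]`.
#' @param grid a [sim_grid()]; `grid$L` is overridden by `params$L`.
#' @param boundary `"free"` (default) or `"clamped"`.
#' @return An object of class `"trajectory_1d"`: list with `times` (s),
#'   node positions `x` (um), and matrices `u`, `v`, `w` (nodes x times;
#'   cytoskeletal displacement um, velocity um/s, substrate displacement um),
#'   `sigma_p` (elements x times, Pa), plus `params`, `protocol`, `grid`.
#' @examples
#' p <- model_params_1d(E = 1000, eta = 3.6e6, gamma = 2e4, kM = 1,
#'                      dsigma = 500, L = 60)
#' pr <- activation_protocol(25, 35)
#' traj <- simulate_1d(p, pr, sim_grid(n_nodes = 61, t_end = 2700))
#' max(abs(traj$v)) * 1000  # peak speed, nm/s
#' @export
simulate_1d <- function(params, protocol, grid = sim_grid(L = params$L),
                        boundary = c("free", "clamped")) {
  stopifnot(inherits(params, "model_params_1d"),
            inherits(protocol, "activation_protocol"))
  boundary <- match.arg(boundary)
  if (protocol$b > params$L)
    stop("activation region [a, b] must lie inside [0, L]", call. = FALSE)
  if (abs(grid$L - params$L) > 1e-9) {
    grid$L <- params$L
    grid$dx <- params$L / (grid$n_nodes - 1)
  }
  res <- .simulate_1d_cpp(params$E, params$eta, params$gamma, params$kM,
                          params$sigma0, params$dsigma, params$L,
                          protocol$a, protocol$b,
                          protocol$t_on, protocol$t_off,
                          protocol$tau_a, protocol$tau_d,
                          grid$n_nodes, grid$dt_step, grid$dt_output,
                          grid$t_end, boundary == "clamped")
  if (!all(is.finite(res$u)))
    stop("1D integration produced non-finite values; reduce dt_step",
         call. = FALSE)
  structure(c(res,
              list(x = seq(0, params$L, length.out = grid$n_nodes),
                   params = params, protocol = protocol, grid = grid,
                   boundary = boundary)),
            class = "trajectory_1d")
}

#' @export
print.trajectory_1d <- function(x, ...) {
  cat(sprintf("1D active Maxwell trajectory: %d nodes x %d time points (0-%g s)\n",
              nrow(x$u), ncol(x$u), max(x$times)))
  cat(sprintf("  peak |v| = %.3g nm/s, peak |u| = %.3g um\n",
              1000 * max(abs(x$v)), max(abs(x$u))))
  invisible(x)
}

#' @export
plot.trajectory_1d <- function(x, what = c("kymograph", "energy"), ...) {
  what <- match.arg(what)
  if (what == "kymograph") {
    image(x = x$times / 60, y = x$x, z = t(x$v) * 1000,
          col = hcl.colors(64, "Blue-Red 3"),
          xlab = "time (min)", ylab = "position (um)",
          main = "flow speed (nm/s)", ...)
  } else {
    tr <- strain_energy_trace(x)
    plot(tr$times / 60, tr$U, type = "l", xlab = "time (min)",
         ylab = "strain energy (Pa um^3)", ...)
  }
  invisible(x)
}

#' Substrate strain energy over time
#'
#' Strain energy stored in the substrate: one half the integral of the
#' traction stress field dotted into the substrate displacement field,
#' `U(t) = 1/2 * integral kM w(x,t)^2 dx` (trapezoidal quadrature).
#'
#' @param traj a [simulate_1d()] trajectory.
#' @param params parameter set; defaults to the one stored in `traj`.
#' @return An object of class `"strain_energy_trace"`: list with `times` (s)
#'   and `U` (Pa um^3).
#' @export
strain_energy_trace <- function(traj, params = traj$params) {
  stopifnot(inherits(traj, "trajectory_1d") || is.list(traj))
  w <- traj$w
  dx <- diff(traj$x[1:2])
  wt <- rep(dx, nrow(w)); wt[1] <- wt[length(wt)] <- dx / 2  # trapezoid
  U <- as.numeric(colSums(w^2 * wt)) * params$kM / 2
  structure(list(times = traj$times, U = U), class = "strain_energy_trace")
}

#' @export
print.strain_energy_trace <- function(x, ...) {
  cat(sprintf("strain-energy trace: %d points, peak U = %.4g\n",
              length(x$U), max(x$U)))
  invisible(x)
}

#' Model flow kymograph
#'
#' Resamples the velocity field of a 1D trajectory onto a space-time grid as
#' a signed-speed kymograph (positive = toward increasing x).
#'
#' @param traj a [simulate_1d()] trajectory.
#' @param dx spatial sampling (um); defaults to the simulation grid spacing.
#' @param dt temporal sampling (s); defaults to the output cadence.
#' @return A [kymograph()] with speeds in um/s.
#' @export
flow_kymograph <- function(traj, dx = NULL, dt = NULL) {
  stopifnot(inherits(traj, "trajectory_1d"))
  if (is.null(dx)) dx <- diff(traj$x[1:2])
  if (is.null(dt)) dt <- diff(traj$times[1:2])
  xs <- seq(0, max(traj$x), by = dx)
  ts <- seq(0, max(traj$times), by = dt)
  # bilinear resample of v onto (xs, ts)
  vi <- apply(traj$v, 2, function(col) approx(traj$x, col, xout = xs)$y)
  if (!isTRUE(all.equal(ts, traj$times))) {
    vi <- t(apply(vi, 1, function(row) approx(traj$times, row, xout = ts)$y))
  }
  kymograph(vi, dx = dx, dt = dt, kind = "speed",
            meta = list(source = "model_1d"))
}

#' Activation-induced point displacement
#'
#' Tracks the model displacement of a material point: `d_act` is the
#' displacement accumulated over the activation period, `d_rel` the residual
#' displacement 15 min (or `relax_window` s) after activation ends.
#'
#' @param traj a [simulate_1d()] trajectory.
#' @param x0 position of the tracked feature (um).
#' @param protocol activation protocol; defaults to the one stored in `traj`.
#' @param relax_window time after `t_off` at which the residual displacement
#'   is read (s).
#' @return named numeric vector `c(d_act =, d_rel =)` in um.
#' @export
point_displacement <- function(traj, x0, protocol = traj$protocol,
                               relax_window = 900) {
  stopifnot(inherits(traj, "trajectory_1d"))
  if (x0 < 0 || x0 > max(traj$x))
    stop("x0 must lie inside [0, L]", call. = FALSE)
  u_at <- function(tq) {
    col <- apply(traj$u, 1, function(row) approx(traj$times, row, xout = tq)$y)
    approx(traj$x, col, xout = x0)$y
  }
  u_on <- u_at(protocol$t_on)
  u_off <- u_at(protocol$t_off)
  u_rel <- u_at(min(protocol$t_off + relax_window, max(traj$times)))
  c(d_act = abs(u_off - u_on), d_rel = abs(u_rel - u_on))
}
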