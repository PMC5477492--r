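#' Rheological parameters of the 1D active Maxwell cell
#'
#' Bundles the material and coupling constants of the one-dimensional
#' contractile-cell model: a continuum of contractile elements in parallel
#' with a Maxwell (spring + dashpot in series) element, coupled to an elastic
#' substrate through friction.
#'
#' @param E elastic modulus of the Maxwell spring (Pa).
#' @param eta viscosity of the Maxwell dashpot (Pa s). The viscoelastic
#'   relaxation time is `eta / E`.
#' @param gamma friction coefficient of the cell-substrate coupling
#'   (Pa s / um).
#' @param kM substrate spring stiffness (Pa / um^2); the traction transmitted
#'   to the substrate is `kM * w` where `w` is the substrate displacement.
#' @param sigma0 spatially uniform baseline active stress (Pa). The model's
#'   reference state treats baseline contractility as already balanced, so
#'   `sigma0 = 0` gives an exact pre-activation steady state; nonzero values
#'   add slow Maxwell creep at free boundaries.
#' @param dsigma amplitude of the additional active stress recruited inside
#'   the activation region (Pa).
#' @param L cell length (um).
#'
#' @return An object of class `"model_params_1d"` (a validated list).
#' @seealso [activation_protocol()], [simulate_1d()], [relaxation_time()]
#' @examples
#' p <- model_params_1d(E = 1000, eta = 3.6e6, gamma = 2e4, kM = 1,
#'                      dsigma = 500, L = 60)
#' relaxation_time(p) / 60  # minutes
#' @export
model_params_1d <- function(E, eta, gamma, kM, sigma0 = 0, dsigma = 0, L = 60) {
  p <- list(E = E, eta = eta, gamma = gamma, kM = kM,
            sigma0 = sigma0, dsigma = dsigma, L = L)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (E <= 0 || eta <= 0 || gamma <= 0 || kM <= 0 || L <= 0)
    stop("E, eta, gamma, kM and L must be strictly positive", call. = FALSE)
  if (sigma0 < 0 || dsigma < 0)
    stop("sigma0 and dsigma must be non-negative", call. = FALSE)
  structure(p, class = "model_params_1d")
}

#' @export
print.model_params_1d <- function(x, ...) {
  cat("1D active Maxwell cell parameters\n")
  cat(sprintf("  E      = %g Pa        eta   = %g Pa s\n", x$E, x$eta))
  cat(sprintf("  gamma  = %g Pa s/um   kM    = %g Pa/um^2\n", x$gamma, x$kM))
  cat(sprintf("  sigma0 = %g Pa        dsigma = %g Pa\n", x$sigma0, x$dsigma))
  cat(sprintf("  L      = %g um        tau = eta/E = %g s (%.3g min)\n",
              x$L, x$eta / x$E, x$eta / x$E / 60))
  invisible(x)
}

#' Viscoelastic relaxation time
#'
#' The ratio of viscosity to elasticity, `eta / E`. Below this timescale the
#' material responds elastically (displacements recoil when load is removed);
#' above it, it flows.
#'
#' @param params a [model_params_1d()] object, or any list with numeric
#'   `eta` and `E` entries.
#' @return relaxation time in seconds.
#' @export
relaxation_time <- function(params) {
  if (is.null(params$E) || is.null(params$eta))
    stop("params must contain 'E' and 'eta'", call. = FALSE)
  if (params$E <= 0) stop("E must be positive", call. = FALSE)
  params$eta / params$E
}

#' Spatio-temporal activation protocol
#'
#' Defines where and when extra contractility is recruited: a spatial interval
#' `[a, b]` inside the cell and an exponentially plateauing temporal ramp that
#' switches on at `t_on`, saturates with time constant `tau_a`, and decays
#' with time constant `tau_d` after `t_off`.
#'
#' @param a,b edges of the activation region (um), `0 <= a < b <= L`.
#' @param t_on,t_off activation switch-on / switch-off times (s).
#' @param tau_a ramp (recruitment) time constant (s).
#' @param tau_d decay time constant after switch-off (s); defaults to 30 s,
#'   matching fast dissipation of recruited contractility once the stimulus
#'   stops.
#' @return An object of class `"activation_protocol"`.
#' @examples
#' activation_protocol(25, 35, t_on = 900, t_off = 1800, tau_a = 120)
#' @export
activation_protocol <- function(a, b, t_on = 900, t_off = 1800,
                                tau_a = 120, tau_d = 30) {
  stopifnot(is.numeric(a), is.numeric(b), a >= 0, b > a,
            t_on < t_off, tau_a > 0, tau_d > 0)
  structure(list(a = a, b = b, t_on = t_on, t_off = t_off,
                 tau_a = tau_a, tau_d = tau_d),
            class = "activation_protocol")
}

#' @export
print.activation_protocol <- function(x, ...) {
  cat(sprintf(
    "Activation protocol: region [%g, %g] um, on %g-%g s (ramp %g s, decay %g s)\n",
    x$a, x$b, x$t_on, x$t_off, x$tau_a, x$tau_d))
  invisible(x)
}

#' Temporal activation ramp
#'
#' The dimensionless time course `f(t)` of recruited contractility: zero
#' before `t_on`, `1 - exp(-(t - t_on)/tau_a)` during activation, and
#' exponential decay with `tau_d` after `t_off`.
#'
#' @param t time(s) in seconds (vectorized).
#' @param protocol an [activation_protocol()].
#' @return numeric vector of ramp values in `[0, 1)`.
#' @export
activation_ramp <- function(t, protocol) {
  p <- protocol
  f <- numeric(length(t))
  act <- t >= p$t_on & t < p$t_off
  post <- t >= p$t_off
  f[act] <- 1 - exp(-(t[act] - p$t_on) / p$tau_a)
  f_off <- 1 - exp(-(p$t_off - p$t_on) / p$tau_a)
  f[post] <- f_off * exp(-(t[post] - p$t_off) / p$tau_d)
  f
}

# analytic time derivative of the ramp; needed by the velocity solve
activation_ramp_rate <- function(t, protocol) {
  p <- protocol
  g <- numeric(length(t))
  act <- t >= p$t_on & t < p$t_off
  post <- t >= p$t_off
  g[act] <- exp(-(t[act] - p$t_on) / p$tau_a) / p$tau_a
  f_off <- 1 - exp(-(p$t_off - p$t_on) / p$tau_a)
  g[post] <- -f_off * exp(-(t[post] - p$t_off) / p$tau_d) / p$tau_d
  g
}

#' Active stress field
#'
#' Total active (contractile) stress at position `x` and time `t`:
#' `sigma0 + dsigma * indicator(a <= x <= b) * f(t)` with `f` the
#' exponentially plateauing ramp of the protocol.
#'
#' @param x position(s) in um, inside `[0, L]`.
#' @param t time in seconds (scalar or same length as `x`).
#' @param params a [model_params_1d()].
#' @param protocol an [activation_protocol()].
#' @return active stress in Pa, vectorized over `x`.
#' @examples
#' p <- model_params_1d(E = 1, eta = 1, gamma = 1, kM = 1, dsigma = 2, L = 10)
#' pr <- activation_protocol(4, 6, t_on = 0, t_off = 100, tau_a = 10)
#' active_stress(5, 10, p, pr)  # 2 * (1 - exp(-1))
#' @export
active_stress <- function(x, t, params, protocol) {
  if (any(x < 0 | x > params$L))
    stop("x must lie inside [0, L]", call. = FALSE)
  if (protocol$b > params$L)
    stop("activation region exceeds the cell length", call. = FALSE)
  inside <- as.numeric(x >= protocol$a & x <= protocol$b)
  params$sigma0 + params$dsigma * inside * activation_ramp(t, protocol)
}

#' Simulation grid for the 1D model
#'
#' @param n_nodes number of spatial nodes (>= 16 for production use; smaller
#'   grids are allowed for analytic limit checks).
#' @param L cell length (um); the node spacing is `L / (n_nodes - 1)`.
#' @param dt_output output sampling interval (s).
#' @param t_end final time (s).
#' @param dt_step internal integrator step (s).
#' @return An object of class `"sim_grid"`.
#' @export
sim_grid <- function(n_nodes = 121, L = 60, dt_output = 20, t_end = 2700,
                     dt_step = 0.5) {
  stopifnot(n_nodes >= 2, L > 0, dt_output > 0, t_end > 0, dt_step > 0)
  structure(list(n_nodes = as.integer(n_nodes), L = L,
                 dx = L / (n_nodes - 1),
                 dt_output = dt_output, t_end = t_end, dt_step = dt_step),
            class = "sim_grid")
}
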