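#' Reference parameter sets for the elastic-like and fluid-like scenes
#'
#' Two frozen parameter sets anchor the synthetic reference scenes:
#'
#' * `"R1"` (elastic-like, wild-type behaviour): relaxation time
#'   `eta/E = 3600 s` (60 min). The remaining constants were calibrated once,
#'   by coarse grid search over `(dsigma, gamma, kM, tau_a)` (see
#'   `inst/scripts/calibrate_reference.R`), to jointly give a tracked feature
#'   5 um outside the activation-zone edge a displacement of ~3 um after
#'   15 min of activation, a residual of ~1 um after 15 min of relaxation,
#'   and mean activation-phase flank flow above 3 nm/s, with a 10 um
#'   activation region and a 15/15/15 min protocol.
#' * `"R2"` (fluid-like, zyxin-null behaviour): identical except that the
#'   Maxwell spring is stiffened so that `eta/E = 1 s`. With the spring
#'   effectively rigid the element reduces to a dashpot of the same
#'   viscosity, which preserves the activation-phase contractile flow while
#'   abolishing the post-activation elastic reversal. (Scaling the viscosity
#'   down instead would shrink the viscous coupling length to well below a
#'   micron and suppress all flank flow, which is not what fluid-like cells
#'   show.)
#'
#' @param set `"R1"` or `"R2"`.
#' @return a [model_params_1d()].
#' @seealso [reference_protocol()], [reference_grid()], [reference_scenes()]
#' @export
reference_params <- function(set = c("R1", "R2")) {
  set <- match.arg(set)
  E <- if (set == "R1") 1000 else 3.6e6   # tau = 3600 s vs 1 s
  model_params_1d(E = E, eta = 3.6e6, gamma = 1.5e4, kM = 30,
                  sigma0 = 0, dsigma = 1530, L = 60)
}

#' @rdname reference_params
#' @export
reference_protocol <- function() {
  activation_protocol(a = 25, b = 35, t_on = 900, t_off = 1800,
                      tau_a = 180, tau_d = 30)
}

#' @rdname reference_params
#' @param n_nodes,dt_output,t_end,dt_step overrides of the default
#'   simulation grid (121 nodes, 20 s output cadence emulating the imaging
#'   interval, 45 min total).
#' @export
reference_grid <- function(n_nodes = 121, dt_output = 20, t_end = 2700,
                           dt_step = 1) {
  sim_grid(n_nodes = n_nodes, L = 60, dt_output = dt_output,
           t_end = t_end, dt_step = dt_step)
}
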