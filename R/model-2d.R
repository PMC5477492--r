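#' Build an equilateral triangular mesh with embedded stress fibres
#'
#' Constructs the discrete 2D cytoskeleton: an equilateral triangular lattice
#' clipped to a `width x height` rectangle, with stress fibres specified as
#' horizontal polylines lying on mesh rows and mapped to chains of lattice
#' links.
#'
#' @param width,height rectangle dimensions (um).
#' @param spacing lattice constant (um); rows are `spacing * sqrt(3)/2`
#'   apart.
#' @param fibre_spec list of fibres, each `c(x0, x1, y)`: a horizontal run
#'   from `x0` to `x1` at height `y`, which must coincide with a mesh row.
#' @return An object of class `"mesh_2d"`: `nodes` (n x 2 matrix, um),
#'   `links` (m x 2 node indices), `rest_length` (m), `boundary` (logical n),
#'   `fibre_links` (list of link-index vectors), `fibre_nodes` (list of
#'   node-index vectors), `spacing`.
#' @examples
#' m <- build_triangular_mesh(4, 2, 1, list(c(0, 4, sqrt(3)/2)))
#' nrow(m$nodes); nrow(m$links)
#' @export
build_triangular_mesh <- function(width, height, spacing,
                                  fibre_spec = list()) {
  stopifnot(spacing > 0, width >= spacing, height >= 0)
  dy <- spacing * sqrt(3) / 2
  rows <- 0:floor(height / dy + 1e-9)
  nodes <- do.call(rbind, lapply(rows, function(j) {
    x0 <- if (j %% 2 == 1) spacing / 2 else 0
    xs <- seq(x0, width + 1e-9, by = spacing)
    cbind(xs, j * dy)
  }))
  colnames(nodes) <- c("x", "y")
  n <- nrow(nodes)

  # link all pairs at lattice distance (n is modest; quadratic scan is fine)
  d2 <- as.matrix(dist(nodes))
  pairs <- which(d2 < 1.001 * spacing & d2 > 0, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  links <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(links) <- NULL
  rest <- sqrt(rowSums((nodes[links[, 1], , drop = FALSE] -
                        nodes[links[, 2], , drop = FALSE])^2))

  # boundary: nodes with fewer than 6 incident links
  deg <- tabulate(c(links), nbins = n)
  boundary <- deg < 6

  link_key <- paste(links[, 1], links[, 2])
  fibre_links <- list(); fibre_nodes <- list()
  for (fs in fibre_spec) {
    stopifnot(length(fs) == 3)
    y <- fs[3]
    row_nodes <- which(abs(nodes[, 2] - y) < 1e-6 * max(1, y))
    if (length(row_nodes) == 0)
      stop("fibre at y = ", y, " does not lie on a mesh row", call. = FALSE)
    sel <- row_nodes[nodes[row_nodes, 1] >= fs[1] - 1e-9 &
                     nodes[row_nodes, 1] <= fs[2] + 1e-9]
    sel <- sel[order(nodes[sel, 1])]
    if (length(sel) < 2)
      stop("fibre spans fewer than two lattice nodes", call. = FALSE)
    ids <- vapply(seq_len(length(sel) - 1), function(i) {
      a <- min(sel[i], sel[i + 1]); b <- max(sel[i], sel[i + 1])
      m <- match(paste(a, b), link_key)
      if (is.na(m)) stop("fibre is off-lattice (non-adjacent nodes)",
                         call. = FALSE)
      m
    }, integer(1))
    fibre_links[[length(fibre_links) + 1]] <- ids
    fibre_nodes[[length(fibre_nodes) + 1]] <- sel
  }

  structure(list(nodes = nodes, links = links, rest_length = rest,
                 boundary = boundary, fibre_links = fibre_links,
                 fibre_nodes = fibre_nodes, spacing = spacing),
            class = "mesh_2d")
}

#' @export
print.mesh_2d <- function(x, ...) {
  cat(sprintf("triangular mesh: %d nodes, %d links, %d stress fibre(s)\n",
              nrow(x$nodes), nrow(x$links), length(x$fibre_links)))
  invisible(x)
}

#' Mesh model parameters
#'
#' @param k_mesh,eta_mesh spring constant (force/strain) and viscosity of
#'   background mesh links (Maxwell elements).
#' @param gamma_node friction of each node against the environment
#'   (force time / length).
#' @param k_SF,eta_SF spring constant and viscosity of stress-fibre links.
#' @param sigma_m active tension (force) applied as an equal-and-opposite
#'   pair (a force dipole) along each activated link.
#' @param mesh_contractile if `TRUE`, activation contracts every link whose
#'   midpoint falls in the region; if `FALSE` (default), only stress-fibre
#'   links contract.
#' @return object of class `"mesh_params_2d"`.
#' @export
mesh_params_2d <- function(k_mesh = 1, eta_mesh = 3600, gamma_node = 5,
                           k_SF = 4, eta_SF = 14400, sigma_m = 0.5,
                           mesh_contractile = FALSE) {
  stopifnot(k_mesh > 0, eta_mesh > 0, gamma_node > 0, k_SF > 0, eta_SF > 0,
            sigma_m >= 0)
  structure(list(k_mesh = k_mesh, eta_mesh = eta_mesh,
                 gamma_node = gamma_node, k_SF = k_SF, eta_SF = eta_SF,
                 sigma_m = sigma_m, mesh_contractile = mesh_contractile),
            class = "mesh_params_2d")
}

#' Rectangular activation region with a temporal ramp
#'
#' @param xlim,ylim region bounds (um).
#' @param t_on,t_off,tau_a,tau_d temporal ramp as in
#'   [activation_protocol()].
#' @return object of class `"activation_region_2d"`; [activation_ramp()]
#'   accepts it.
#' @export
activation_region_2d <- function(xlim, ylim, t_on = 900, t_off = 1800,
                                 tau_a = 180, tau_d = 30) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, xlim[1] < xlim[2],
            ylim[1] < ylim[2], t_on < t_off, tau_a > 0, tau_d > 0)
  structure(list(xlim = xlim, ylim = ylim, t_on = t_on, t_off = t_off,
                 tau_a = tau_a, tau_d = tau_d),
            class = "activation_region_2d")
}

#' Simulate the 2D discrete cytoskeleton
#'
#' Overdamped dynamics of a triangular mesh of viscoelastic cables: each
#' link is a Maxwell element (elastic force `k * (l - l_r)` with rest-length
#' flow `dl_r/dt = (k/eta) * (l - l_r)`), and activated links additionally
#' carry a contractile force dipole `sigma_m * f(t)` pulling their end nodes
#' together. Node positions obey `gamma_node * dX/dt = sum of link forces`.
#' Integration is explicit Euler; the step is capped at
#' `0.2 * gamma_node / k_max` and halved adaptively if any node moves more
#' than a tenth of the lattice spacing in one step.
#'
#' @param mesh a [build_triangular_mesh()] mesh.
#' @param params a [mesh_params_2d()].
#' @param region an [activation_region_2d()]; links whose midpoint falls in
#'   the rectangle are activated (all links if `mesh_contractile`, stress
#'   fibre links only otherwise).
#' @param dt requested time step (s); reduced if unstable.
#' @param t_end simulation end (s).
#' @param dt_output output cadence (s).
#' @param pin_boundary pin boundary nodes (for strip comparisons against the
#'   1D continuum); default free.
#' @return object of class `"trajectory_2d"`: `times`, `pos` (n x 2 x T
#'   array), `mesh`, `params`, `region`.
#' @export
simulate_2d <- function(mesh, params, region, dt = NULL, t_end = 2700,
                        dt_output = 20, pin_boundary = FALSE) {
  stopifnot(inherits(mesh, "mesh_2d"), inherits(params, "mesh_params_2d"),
            inherits(region, "activation_region_2d"))
  m <- nrow(mesh$links)
  n <- nrow(mesh$nodes)
  is_sf <- rep(FALSE, m)
  for (ids in mesh$fibre_links) is_sf[ids] <- TRUE
  k <- ifelse(is_sf, params$k_SF, params$k_mesh)
  eta <- ifelse(is_sf, params$eta_SF, params$eta_mesh)

  dt_stable <- 0.2 * params$gamma_node / max(k)
  if (is.null(dt)) dt <- dt_stable
  dt <- min(dt, dt_stable)
  sub <- max(1L, as.integer(ceiling(dt_output / dt - 1e-9)))
  h <- dt_output / sub
  n_out <- floor(t_end / dt_output + 1e-9) + 1

  X <- mesh$nodes
  lr <- mesh$rest_length
  i1 <- mesh$links[, 1]; i2 <- mesh$links[, 2]

  mid <- (X[i1, , drop = FALSE] + X[i2, , drop = FALSE]) / 2
  in_region <- mid[, 1] >= region$xlim[1] & mid[, 1] <= region$xlim[2] &
               mid[, 2] >= region$ylim[1] & mid[, 2] <= region$ylim[2]
  activated <- if (params$mesh_contractile) in_region else in_region & is_sf

  free <- if (pin_boundary) !mesh$boundary else rep(TRUE, n)
  pos <- array(NA_real_, c(n, 2, n_out))
  times <- numeric(n_out)
  out <- 1L
  pos[, , 1] <- X
  t <- 0
  max_move <- 0.1 * mesh$spacing

  step_once <- function(X, lr, t, h) {
    dvec <- X[i2, , drop = FALSE] - X[i1, , drop = FALSE]
    len <- sqrt(rowSums(dvec^2))
    ux <- dvec[, 1] / len; uy <- dvec[, 2] / len
    f <- activation_ramp(t, region)
    tension <- k * (len - lr) + params$sigma_m * f * activated
    Fx <- numeric(n); Fy <- numeric(n)
    fx <- tension * ux; fy <- tension * uy
    # node i1 is pulled toward i2 and vice versa
    Fx <- Fx + tabulate_add(i1, fx, n) - tabulate_add(i2, fx, n)
    Fy <- Fy + tabulate_add(i1, fy, n) - tabulate_add(i2, fy, n)
    V <- cbind(Fx, Fy) / params$gamma_node
    V[!free, ] <- 0
    list(X = X + h * V, lr = lr + h * (k / eta) * (len - lr),
         move = max(abs(h * V)))
  }

  for (s in seq_len((n_out - 1) * sub)) {
    st <- step_once(X, lr, t, h)
    if (st$move > max_move) {
      # adaptive fallback: substep
      nsub <- ceiling(st$move / max_move)
      hh <- h / nsub
      for (q in seq_len(nsub)) {
        st <- step_once(X, lr, t + (q - 1) * hh, hh)
        X <- st$X; lr <- st$lr
      }
    } else {
      X <- st$X; lr <- st$lr
    }
    t <- t + h
    if (!all(is.finite(X)))
      stop("2D integration diverged; reduce dt below ",
           format(dt_stable), call. = FALSE)
    if (s %% sub == 0) {
      out <- out + 1L
      pos[, , out] <- X
      times[out] <- t
    }
  }
  structure(list(times = times, pos = pos, mesh = mesh, params = params,
                 region = region, activated = activated),
            class = "trajectory_2d")
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  tmp <- rowsum(val, idx)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

#' @export
print.trajectory_2d <- function(x, ...) {
  disp <- sqrt(rowSums((x$pos[, , dim(x$pos)[3]] - x$pos[, , 1])^2))
  cat(sprintf("2D mesh trajectory: %d nodes x %d frames, max displacement %.3g um\n",
              dim(x$pos)[1], dim(x$pos)[3], max(disp)))
  invisible(x)
}

#' Transverse pinch of paired stress fibres
#'
#' Measures how much two parallel stress fibres move toward each other
#' perpendicular to their orientation: the peak reduction (over the time
#' window) of the mean inter-fibre perpendicular distance, averaged over the
#' activation span. Contractile background meshes pinch fibres together;
#' fibre-only contractility leaves the transverse spacing unchanged.
#'
#' @param traj a [simulate_2d()] trajectory whose mesh has >= 2 fibres.
#' @param window time window (s, length 2) over which to seek the peak;
#'   defaults to the activation period.
#' @return peak transverse distance reduction (um).
#' @export
transverse_pinch_metric <- function(traj, window = NULL) {
  mesh <- traj$mesh
  if (length(mesh$fibre_nodes) < 2)
    stop("need at least two stress fibres", call. = FALSE)
  if (is.null(window)) window <- c(traj$region$t_on, traj$region$t_off)
  f1 <- mesh$fibre_nodes[[1]]; f2 <- mesh$fibre_nodes[[2]]
  span <- traj$region$xlim
  sel1 <- f1[mesh$nodes[f1, 1] >= span[1] & mesh$nodes[f1, 1] <= span[2]]
  sel2 <- f2[mesh$nodes[f2, 1] >= span[1] & mesh$nodes[f2, 1] <= span[2]]
  dist_at <- function(ti) {
    y1 <- mean(traj$pos[sel1, 2, ti]); y2 <- mean(traj$pos[sel2, 2, ti])
    abs(y1 - y2)
  }
  d0 <- dist_at(1)
  idx <- which(traj$times >= window[1] & traj$times <= window[2])
  if (length(idx) == 0) return(0)
  max(0, max(d0 - vapply(idx, dist_at, numeric(1))))
}
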