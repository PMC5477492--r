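#' Ordinary kriging interpolation of scattered vectors
#'
#' Interpolates scattered vector samples onto a regular grid by ordinary
#' kriging, per component, with an exponential variogram fitted to the
#' empirical semivariogram. Kriging without nugget is an exact interpolator:
#' predictions at the data points reproduce the data. If the kriging system
#' is singular (e.g. duplicated points), the function falls back to
#' inverse-multiquadric radial-basis interpolation with a warning.
#'
#' @param points n x 2 matrix of sample locations (um).
#' @param values n x 2 matrix of vector samples (ux, uy).
#' @param gx,gy grid coordinates (um) of the target regular grid.
#' @param n_bins number of semivariogram distance bins.
#' @return a `"displacement"` [vector_field_2d()] on the `(gx, gy)` grid
#'   with spacing `gx[2] - gx[1]`.
#' @export
krige_interpolate <- function(points, values, gx, gy, n_bins = 15) {
  points <- as.matrix(points); values <- as.matrix(values)
  stopifnot(ncol(points) == 2, nrow(points) == nrow(values),
            ncol(values) == 2)
  if (nrow(points) < 10)
    stop("kriging needs at least 10 sample points", call. = FALSE)
  n <- nrow(points)
  D <- as.matrix(dist(points))

  grid <- as.matrix(expand.grid(x = gx, y = gy))
  # cross distances grid x data
  Dg <- sqrt(outer(grid[, 1], points[, 1], "-")^2 +
             outer(grid[, 2], points[, 2], "-")^2)

  comp <- lapply(1:2, function(j) {
    z <- values[, j]
    if (diff(range(z)) < 1e-12)          # constant field: unbiasedness
      return(rep(z[1], nrow(grid)))
    vg <- fit_exp_variogram(D, z, n_bins)
    C <- vg$sill * exp(-D / vg$range)            # no-nugget covariance
    K <- rbind(cbind(C, 1), c(rep(1, n), 0))
    Cg <- vg$sill * exp(-Dg / vg$range)
    rhs <- t(cbind(Cg, 1))
    Wt <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(Wt)) {
      warning("singular kriging system; falling back to RBF interpolation")
      return(rbf_interp(points, z, grid))
    }
    as.numeric(crossprod(Wt[1:n, , drop = FALSE], z))
  })
  ux <- matrix(comp[[1]], length(gy), length(gx), byrow = TRUE)
  uy <- matrix(comp[[2]], length(gy), length(gx), byrow = TRUE)
  vector_field_2d(ux, uy, gx[2] - gx[1], "displacement",
                  origin = c(gx[1], gy[1]))
}

# fit gamma(h) = sill * (1 - exp(-h/range)) to the empirical semivariogram
fit_exp_variogram <- function(D, z, n_bins) {
  dz2 <- 0.5 * outer(z, z, "-")^2
  h <- D[upper.tri(D)]
  g <- dz2[upper.tri(dz2)]
  hmax <- max(h) / 2
  bins <- seq(0, hmax, length.out = n_bins + 1)
  bi <- cut(h, bins, labels = FALSE)
  ok <- !is.na(bi)
  gh <- tapply(g[ok], bi[ok], mean)
  hm <- tapply(h[ok], bi[ok], mean)
  s0 <- max(var(z), 1e-12)
  r0 <- hmax / 3
  fit <- tryCatch(
    optim(log(c(s0, r0)), function(lp) {
      p <- exp(lp)
      sum((p[1] * (1 - exp(-hm / p[2])) - gh)^2)
    }, method = "Nelder-Mead")$par,
    error = function(e) log(c(s0, r0)))
  list(sill = exp(fit[1]), range = exp(fit[2]))
}

rbf_interp <- function(points, z, grid) {
  eps <- max(dist(points)) / sqrt(nrow(points))
  phi <- function(r) sqrt(r^2 + eps^2)
  A <- phi(as.matrix(dist(points)))
  wts <- solve(A + diag(1e-10, nrow(A)), z)
  Dg <- sqrt(outer(grid[, 1], points[, 1], "-")^2 +
             outer(grid[, 2], points[, 2], "-")^2)
  as.numeric(phi(Dg) %*% wts)
}
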