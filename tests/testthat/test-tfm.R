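sub <- substrate_props()   # 8.6 kPa gel, nu = 0.5

test_that("forward Boussinesq operator matches closed forms", {
  n <- 64; sp <- 0.5
  T0 <- vector_field_2d(matrix(0, n, n), matrix(0, n, n), sp, "traction")
  u0 <- greens_forward(T0, sub)
  expect_equal(max(abs(u0$vx)), 0)

  # single Fourier mode: u is the same mode scaled by the G(k) entry
  x <- (seq_len(n) - 1) * sp
  kx <- 2 * pi * 4 / (n * sp)
  tx <- matrix(sin(kx * x), n, n, byrow = TRUE)
  Tm <- vector_field_2d(tx, matrix(0, n, n), sp, "traction")
  um <- greens_forward(Tm, sub)
  g_entry <- (1 - sub$nu) / (sub$mu * kx)   # ky = 0 mode of the tensor
  expect_equal(um$vx, tx * g_entry, tolerance = 1e-10)
  expect_lt(max(abs(um$vy)), 1e-12 * max(abs(um$vx)))

  # equal-and-opposite point-force pair: antisymmetric displacement
  tx2 <- matrix(0, n, n)
  tx2[33, 25] <- 1000; tx2[33, 41] <- -1000
  Tp <- vector_field_2d(tx2, matrix(0, n, n), sp, "traction")
  up <- greens_forward(Tp, sub)
  # antisymmetry about the midpoint (col 33) along the pair axis
  expect_equal(up$vx[33, 33 + 1:7], -up$vx[33, 33 - 1:7],
               tolerance = 1e-8)
})

test_that("forward operator agrees with real-space Cerruti convolution", {
  # oracle: direct summation of the Cerruti point-force solution
  # u_x(r) = (1+nu)/(2 pi E_y) * [ 2(1-nu)/r + 2 nu x^2/r^3 ] * F, with
  # E_y = 2 mu (1+nu):  u_x = F/(2 pi mu) [ (1-nu)/r + nu x^2 / r^3 ]
  n <- 96; sp <- 0.5
  tx <- matrix(0, n, n)
  centres <- cbind(c(45, 53), c(40, 58))   # dipole rows, cols
  F <- c(800, -800) * sp^2                 # point forces (Pa um^2)
  tx[centres[1, 1], centres[1, 2]] <- 800
  tx[centres[2, 1], centres[2, 2]] <- -800
  Tp <- vector_field_2d(tx, matrix(0, n, n), sp, "traction")
  up <- greens_forward(Tp, sub)

  cerruti_ux <- function(x, y) {
    out <- 0
    for (i in 1:2) {
      dx <- (x - centres[i, 2]) * sp
      dy <- (y - centres[i, 1]) * sp
      r <- sqrt(dx^2 + dy^2)
      out <- out + F[i] / (2 * pi * sub$mu) *
        ((1 - sub$nu) / r + sub$nu * dx^2 / r^3)
    }
    out
  }
  # compare at probe points a few um from the forces (far from the image
  # boundary; the FFT operator is periodic, the oracle is free-space, so
  # agreement is expected only to ~10% at moderate range)
  probes <- rbind(c(49, 49), c(44, 52), c(56, 47))
  for (k in seq_len(nrow(probes))) {
    ux_fft <- up$vx[probes[k, 1], probes[k, 2]]
    ux_ora <- cerruti_ux(probes[k, 2], probes[k, 1])
    expect_equal(ux_fft, ux_ora, tolerance = 0.15)
  }
})

test_that("regularized inversion round-trips the forward operator", {
  sc <- gen_bead_scene(n_px = 96, seed = 3, noise = FALSE)
  Tt <- sc$truth$traction[[1]]
  ut <- sc$truth$displacement[[1]]
  Tr <- fttc_inverse(ut, sub, lam = 0)
  relerr <- sqrt(sum((Tr$vx - Tt$vx)^2 + (Tr$vy - Tt$vy)^2) /
                   sum(Tt$vx^2 + Tt$vy^2))
  expect_lt(relerr, 0.05)
  # zero displacement, zero traction
  u0 <- vector_field_2d(matrix(0, 16, 16), matrix(0, 16, 16), 1,
                        "displacement")
  expect_equal(max(abs(fttc_inverse(u0, sub, 1e-4)$vx)), 0)
  expect_error(fttc_inverse(ut, sub, lam = -1), "non-negative")

  # zero net force on any input
  set.seed(4)
  un <- vector_field_2d(matrix(rnorm(32^2), 32), matrix(rnorm(32^2), 32),
                        1, "displacement")
  Tn <- fttc_inverse(un, sub, 1e-5)
  dA <- 1
  expect_lt(abs(sum(Tn$vx) * dA), 1e-9 * sum(abs(Tn$vx)) * dA)
  expect_lt(abs(sum(Tn$vy) * dA), 1e-9 * sum(abs(Tn$vy)) * dA)

  # linearity / superposition of forward and inverse operators
  ua <- vector_field_2d(matrix(rnorm(32^2), 32), matrix(rnorm(32^2), 32),
                        1, "displacement")
  Tsum <- fttc_inverse(vector_field_2d(un$vx + 2 * ua$vx,
                                       un$vy + 2 * ua$vy, 1,
                                       "displacement"), sub, 1e-5)
  Ta <- fttc_inverse(ua, sub, 1e-5)
  expect_equal(Tsum$vx, Tn$vx + 2 * Ta$vx, tolerance = 1e-10)
})

test_that("regularization-weight selection tracks the true-error optimum", {
  sc <- gen_bead_scene(n_px = 128, seed = 7, noise = FALSE)
  ut <- sc$truth$displacement[[1]]
  Tt <- sc$truth$traction[[1]]
  lams <- 10^seq(-7, -3, length.out = 24)

  sel0 <- lcurve_select(ut, sub, lams)
  # noiseless data: residual norm non-decreasing, solution norm
  # non-increasing, chosen weight in the smallest decade
  expect_true(all(diff(sel0$residual_norm) > -1e-9))
  expect_true(all(diff(sel0$solution_norm) < 1e-9))
  expect_lte(sel0$lam, lams[1] * 10)

  # bead-position noise of 0.05 px: chosen lam within one decade of the
  # weight minimizing the true traction error (brute force)
  set.seed(8)
  noise <- 0.05 * sc$pixel_size
  un <- vector_field_2d(ut$vx + rnorm(length(ut$vx), sd = noise),
                        ut$vy + rnorm(length(ut$vy), sd = noise),
                        ut$spacing, "displacement")
  sel <- lcurve_select(un, sub, lams)
  errs <- vapply(lams, function(l) {
    Tl <- fttc_inverse(un, sub, l)
    sqrt(sum((Tl$vx - Tt$vx)^2 + (Tl$vy - Tt$vy)^2))
  }, numeric(1))
  expect_lt(abs(log10(sel$lam) - log10(lams[which.min(errs)])), 1)
})

test_that("strain energy matches the independent summation oracle", {
  u0 <- vector_field_2d(matrix(0, 8, 8), matrix(0, 8, 8), 2,
                        "displacement")
  T1 <- vector_field_2d(matrix(3, 8, 8), matrix(1, 8, 8), 2, "traction")
  expect_equal(strain_energy_2d(T1, u0), 0)
  # uniform fields: U = (T . u) A / 2
  u1 <- vector_field_2d(matrix(0.2, 8, 8), matrix(-0.1, 8, 8), 2,
                        "displacement")
  A <- 8 * 8 * 4
  expect_equal(strain_energy_2d(T1, u1), 0.5 * (3 * 0.2 - 1 * 0.1) * A)
  # random smooth fields vs elementwise loop
  set.seed(5)
  tx <- EBImage::gblur(matrix(rnorm(24^2), 24), 2)
  ty <- EBImage::gblur(matrix(rnorm(24^2), 24), 2)
  ux <- EBImage::gblur(matrix(rnorm(24^2), 24), 2)
  uy <- EBImage::gblur(matrix(rnorm(24^2), 24), 2)
  acc <- 0
  for (i in 1:24) for (j in 1:24)
    acc <- acc + tx[i, j] * ux[i, j] + ty[i, j] * uy[i, j]
  expect_equal(strain_energy_2d(
    vector_field_2d(tx, ty, 0.5, "traction"),
    vector_field_2d(ux, uy, 0.5, "displacement")), 0.5 * acc * 0.25)
  expect_error(strain_energy_2d(
    vector_field_2d(tx, ty, 0.5, "traction"), u1), "match")
})

test_that("PIV recovers imposed shifts to sub-pixel accuracy", {
  ps <- 0.215; n <- 192
  set.seed(6)
  nb <- round(2.5 * (n * ps)^2)
  bx <- runif(nb, 2, n * ps - 2); by <- runif(nb, 2, n * ps - 2)
  amp <- runif(nb, 0.6, 1.4)
  ref <- render_beads(bx, by, amp, n, ps)

  # identical images: zero field
  f0 <- piv_beads(ref, ref, ps, window = 16, search = 6)
  expect_equal(max(abs(c(f0$vx, f0$vy))), 0)

  # integer shift of 3 px
  def3 <- render_beads(bx + 3 * ps, by, amp, n, ps)
  f3 <- piv_beads(ref, def3, ps, window = 16, search = 6)
  expect_lt(abs(median(f3$vx) / ps - 3), 0.05)

  # half-pixel shift recovered within 0.1 px RMS
  def5 <- render_beads(bx + 0.5 * ps, by, amp, n, ps)
  f5 <- piv_beads(ref, def5, ps, window = 16, search = 6)
  expect_lt(sqrt(mean((f5$vx / ps - 0.5)^2)), 0.1)
  expect_lt(sqrt(mean((f5$vy / ps)^2)), 0.1)
})

test_that("kriging is an exact interpolator with known-function accuracy", {
  set.seed(9)
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 10))
  # constant field stays constant everywhere
  vals <- cbind(rep(2.5, 50), rep(-1, 50))
  g <- seq(0.5, 9.5, by = 0.5)
  fc <- krige_interpolate(pts, vals, g, g)
  expect_equal(max(abs(fc$vx - 2.5)), 0, tolerance = 1e-6)
  expect_equal(max(abs(fc$vy + 1)), 0, tolerance = 1e-6)

  # linear trend: grid RMS error < 2% of the range
  lin <- function(x, y) 0.3 * x - 0.1 * y + 1
  vals2 <- cbind(lin(pts[, 1], pts[, 2]), -lin(pts[, 1], pts[, 2]))
  fl <- krige_interpolate(pts, vals2, g, g)
  truth <- outer(g, g, function(yy, xx) lin(xx, yy))
  rng <- diff(range(truth))
  expect_lt(sqrt(mean((fl$vx - truth)^2)), 0.02 * rng)

  expect_error(krige_interpolate(pts[1:5, ], vals2[1:5, ], g, g),
               "at least 10")
})

test_that("kriged values reproduce the data at sample locations", {
  set.seed(10)
  n <- 30
  pts <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  z <- sin(pts[, 1]) + 0.3 * pts[, 2]
  vals <- cbind(z, -z)
  # krige onto a grid built from the sample coordinates themselves
  fg <- krige_interpolate(pts, vals, sort(pts[, 1]), sort(pts[, 2]))
  pred <- fg$vx[cbind(rank(pts[, 2]), rank(pts[, 1]))]
  expect_lt(max(abs(pred - z)), 1e-6)
})

test_that("end-to-end traction microscopy recovers the stored strain energy", {
  sc <- gen_bead_scene(seed = 1, noise = FALSE)
  ps <- sc$pixel_size
  fov <- dim(sc$reference)[1] * ps
  piv <- piv_beads(sc$reference, sc$deformed[1, , ], pixel_size = ps,
                   window = 16, search = 8)
  xs <- piv$origin[1] + (seq_len(ncol(piv$vx)) - 1) * piv$spacing
  ys <- piv$origin[2] + (seq_len(nrow(piv$vx)) - 1) * piv$spacing
  uk <- krige_interpolate(as.matrix(expand.grid(x = xs, y = ys)),
                          cbind(as.vector(t(piv$vx)),
                                as.vector(t(piv$vy))),
                          seq(0.43, fov - 0.43, by = 0.86),
                          seq(0.43, fov - 0.43, by = 0.86))
  sel <- lcurve_select(uk, sub, 10^seq(-7, -3, length.out = 24))
  Tr <- fttc_inverse(uk, sub, sel$lam)
  U <- strain_energy_2d(Tr, uk)
  expect_equal(U / sc$truth$strain_energy, 1, tolerance = 0.15)
})
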