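test_that("optical flow satisfies the translation-accuracy contract", {
  img <- textured_image(96)
  stack <- array(0, c(2, 96, 96))
  stack[1, , ] <- img
  stack[2, , ] <- img
  # identical frames: zero flow
  fl0 <- optical_flow(stack)
  expect_equal(max(abs(c(fl0$vx, fl0$vy))), 0)

  # global translation of (1, 0) px recovered within 0.1 px
  xs <- seq_len(96)
  shifted <- t(apply(img, 1, function(r) approx(xs, r, xout = xs - 1,
                                                rule = 2)$y))
  stack[2, , ] <- shifted
  fl <- optical_flow(stack)
  inner <- 12:84
  expect_equal(mean(fl$vx[1, inner, inner]), 1, tolerance = 0.1)
  expect_lt(abs(mean(fl$vy[1, inner, inner])), 0.1)

  # 2 px translation through the pyramid
  shifted2 <- t(apply(img, 1, function(r) approx(xs, r, xout = xs - 2,
                                                 rule = 2)$y))
  stack[2, , ] <- shifted2
  fl2 <- optical_flow(stack)
  expect_equal(mean(fl2$vx[1, inner, inner]), 2, tolerance = 0.1)

  # the block-matching fallback obeys the same contract
  flb <- optical_flow(stack, method = "block")
  expect_equal(mean(flb$vx[1, inner, inner]), 2, tolerance = 0.1)
})

test_that("optical flow recovers the generator's advection on the fibre", {
  # compare the time-integrated projected flow over the activation phase
  # with the generator's Eulerian displacement field (plus the baseline
  # drift) on the activation flanks
  sc <- small_fibre_scene(noise = FALSE)
  pre <- preprocess_stack(sc$stack, sigma_t = 0)
  fl <- optical_flow(pre)
  W <- dim(sc$stack)[3]
  m <- sc$truth$margin_px
  path <- fibre_path(cbind(c(m + 1, W - m), sc$truth$fibre_row))
  k <- project_flow(fl, path, pixel_size = sc$pixel_size, dt = sc$dt)
  xs <- fibremech:::kymo_space(k)
  ts <- fibremech:::kymo_time(k)
  act <- ts >= 900 & ts < 1800
  disp_est <- rowSums(k$values[, act]) * sc$dt
  tr <- sc$truth$trajectory
  ue <- apply(tr$u, 1, function(row)
    approx(tr$times, row, xout = c(900, 1800))$y)
  cellx <- xs + 0.5 * sc$pixel_size
  du_tru <- approx(tr$x, ue[2, ] - ue[1, ], xout = cellx, rule = 2)$y -
    0.001 * sign(cellx - 15) * 900
  flank <- (cellx > 19 & cellx < 25) | (cellx > 5 & cellx < 11)
  relrms <- sqrt(mean((disp_est[flank] - du_tru[flank])^2) /
                   mean(du_tru[flank]^2))
  expect_lt(relrms, 0.15)
})

test_that("kymograph extraction follows path geometry and width averaging", {
  # constant stack: constant kymograph
  stack <- array(5, c(4, 40, 60))
  path <- fibre_path(cbind(c(10, 50), c(20, 20)))
  k <- extract_kymograph(stack, path, pixel_size = 0.1, dt = 10)
  expect_equal(max(abs(k$values - 5)), 0)
  expect_equal(k$dx, 0.1)

  # a bright spot moving at constant speed produces a ridge of that slope
  nf <- 12
  stack2 <- array(0, c(nf, 40, 60))
  v_px <- 1.5
  for (f in seq_len(nf)) {
    cx <- 12 + v_px * (f - 1)
    stack2[f, , ] <- outer(exp(-((1:40) - 20)^2 / 8),
                           exp(-((1:60) - cx)^2 / 8))
  }
  k2 <- extract_kymograph(stack2, path, pixel_size = 1, dt = 1)
  ridge <- apply(k2$values, 2, which.max)
  slope <- coef(lm(ridge ~ seq_len(nf)))[2]
  expect_equal(unname(slope), v_px, tolerance = 0.05 * v_px)

  # width averaging of a cross-section-uniform image changes nothing
  k1 <- extract_kymograph(stack2, path, width = 1, pixel_size = 1, dt = 1)
  stack3 <- stack2
  for (f in seq_len(nf)) stack3[f, , ] <- matrix(stack2[f, 20, ], 40, 60,
                                                 byrow = TRUE)
  kw1 <- extract_kymograph(stack3, path, width = 1, pixel_size = 1, dt = 1)
  kw9 <- extract_kymograph(stack3, path, width = 9, pixel_size = 1, dt = 1)
  expect_equal(kw9$values, kw1$values, tolerance = 1e-12)
})

test_that("kymograph extraction is invariant to path orientation", {
  img <- textured_image(80, seed = 7)
  stack <- array(0, c(2, 80, 80)); stack[1, , ] <- img; stack[2, , ] <- img
  path_h <- fibre_path(cbind(c(20, 60), c(40, 40)))
  k_h <- extract_kymograph(stack, path_h, pixel_size = 1, dt = 1)
  # rotate image and path by 90 degrees
  img_r <- t(img)[, 80:1]   # 90 deg rotation
  stack_r <- array(0, c(2, 80, 80))
  stack_r[1, , ] <- img_r; stack_r[2, , ] <- img_r
  path_v <- fibre_path(cbind(c(80 - 40 + 1, 80 - 40 + 1), c(20, 60)))
  k_v <- extract_kymograph(stack_r, path_v, pixel_size = 1, dt = 1)
  expect_equal(dim(k_v$values), dim(k_h$values))
  relerr <- max(abs(k_v$values - k_h$values)) / diff(range(k_h$values))
  expect_lt(relerr, 0.01)
})

test_that("flow projection onto the fibre gives signed speeds", {
  # uniform flow parallel to a straight path: constant kymograph = speed
  fl <- list(vx = array(2, c(3, 30, 50)), vy = array(0, c(3, 30, 50)))
  class(fl) <- "flow_field"
  path <- fibre_path(cbind(c(5, 45), c(15, 15)))
  k <- project_flow(fl, path, pixel_size = 0.5, dt = 10)
  expect_equal(max(abs(k$values - 2 * 0.5 / 10)), 0, tolerance = 1e-12)
  # flow perpendicular to the path projects to zero
  fl$vx <- array(0, c(3, 30, 50)); fl$vy <- array(3, c(3, 30, 50))
  k0 <- project_flow(fl, path, pixel_size = 0.5, dt = 10)
  expect_lt(max(abs(k0$values)), 1e-12)
})

test_that("projected flow reverses on both flanks after activation ends", {
  sc <- small_fibre_scene(noise = FALSE)
  pre <- preprocess_stack(sc$stack, sigma_t = 0)
  fl <- optical_flow(pre)
  W <- dim(sc$stack)[3]
  m <- sc$truth$margin_px
  path <- fibre_path(cbind(c(m + 1, W - m), sc$truth$fibre_row))
  k <- project_flow(fl, path, pixel_size = sc$pixel_size, dt = sc$dt)
  xs <- fibremech:::kymo_space(k)
  ts <- fibremech:::kymo_time(k)
  act <- ts > 1000 & ts < 1790
  rel <- ts >= 1800 & ts <= 2200
  left <- xs > 7 & xs < 12    # flank left of region [12, 18]
  right <- xs > 18 & xs < 23
  expect_gt(mean(k$values[left, act]), 0)    # toward the region
  expect_lt(mean(k$values[right, act]), 0)
  expect_lt(mean(k$values[left, rel]), 0)    # reversal
  expect_gt(mean(k$values[right, rel]), 0)
})

test_that("structure tensor orientation matches constructed fibres", {
  # straight fibre at 30 degrees
  n <- 80
  ang <- 30 * pi / 180
  xs <- matrix(rep(1:n, each = n), n) - n / 2
  ys <- matrix(rep(1:n, n), n) - n / 2
  d <- abs(-sin(ang) * xs + cos(ang) * ys)   # distance to the fibre line
  img <- exp(-d^2 / 4)
  om <- orientation_map(img, scale = 3)
  on_fibre <- d < 1.5
  # orientation convention: y = rows, angles modulo pi
  ang_err <- abs(((om$orientation[on_fibre] - ang + pi / 2) %% pi) - pi / 2)
  expect_lt(median(ang_err) * 180 / pi, 2)
  expect_gt(median(om$coherence[on_fibre]), 0.8)

  # isotropic noise: low coherence
  set.seed(2)
  om_n <- orientation_map(matrix(runif(n * n), n), scale = 3)
  expect_lt(median(om_n$coherence), 0.2)

  # rotating the fibre rotates the recovered orientation
  ang2 <- 75 * pi / 180
  d2 <- abs(-sin(ang2) * xs + cos(ang2) * ys)
  om2 <- orientation_map(exp(-d2^2 / 4), scale = 3)
  on2 <- d2 < 1.5
  rot_err <- abs(((om2$orientation[on2] - om$orientation[on_fibre][1] -
                     (ang2 - ang) + pi / 2) %% pi) - pi / 2)
  expect_lt(median(rot_err) * 180 / pi, 3)
})

test_that("recovered flow aligns with fibre orientation during activation", {
  sc <- small_fibre_scene(noise = FALSE)
  pre <- preprocess_stack(sc$stack[50:54, , ], sigma_t = 0)
  fl <- optical_flow(pre)
  om <- orientation_map(pre[1, , ], scale = 3)
  mask <- pre[1, , ] > quantile(pre[1, , ], 0.9)
  vx <- fl$vx[2, , ][mask]; vy <- fl$vy[2, , ][mask]
  speed <- sqrt(vx^2 + vy^2)
  keep <- speed > quantile(speed, 0.5)
  flow_ang <- atan2(vy[keep], vx[keep])
  fib_ang <- om$orientation[mask][keep]
  dev <- abs(((flow_ang - fib_ang + pi / 2) %% pi) - pi / 2)
  expect_lt(median(dev) * 180 / pi, 15)
})
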