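test_that("recruitment traces normalize and cancel shared bleaching", {
  H <- 40; W <- 40
  roi <- matrix(FALSE, H, W); roi[10:18, 10:18] <- TRUE
  ctl <- matrix(FALSE, H, W); ctl[25:33, 25:33] <- TRUE
  bg <- matrix(FALSE, H, W); bg[2:6, 2:6] <- TRUE
  nf <- 30
  times <- (seq_len(nf) - 1) * 60

  # constant everything: normalized trace is 1 (and a warning, since the
  # control does not decay)
  stack <- array(10, c(nf, H, W))
  for (f in seq_len(nf)) {
    img <- stack[f, , ]; img[roi] <- 50; img[ctl] <- 40
    stack[f, , ] <- img
  }
  expect_warning(tr <- recruitment_trace(stack, roi, ctl, bg, times,
                                         baseline_window = c(0, 600)),
                 "does not decay")
  expect_equal(tr$normalized, rep(1, nf), tolerance = 1e-12)

  # shared exponential bleaching cancels
  bleach <- exp(-times / 1200)
  stack2 <- array(0, c(nf, H, W))
  for (f in seq_len(nf)) {
    img <- matrix(10, H, W)
    img[roi] <- 10 + 40 * bleach[f]
    img[ctl] <- 10 + 30 * bleach[f]
    stack2[f, , ] <- img
  }
  tr2 <- recruitment_trace(stack2, roi, ctl, bg, times,
                           baseline_window = c(0, 600))
  expect_lt(max(abs(tr2$normalized - 1)), 0.01)
  expect_error(recruitment_trace(stack2, roi, roi, bg, times), "disjoint")
})

test_that("configured recruitment fold-increase is recovered from a scene", {
  # scene with recruitment only (no contraction, no drift), so the ROI
  # intensity isolates the configured accumulation amplitude
  p <- model_params_1d(E = 1000, eta = 3.6e6, gamma = 1.5e4, kM = 30,
                       dsigma = 0, L = 30)
  pr <- activation_protocol(12, 18, 900, 1800, 180, 30)
  sc <- gen_fibre_movie(p, pr, seed = 5, pixel_size = 0.108,
                        height_px = 32, drift = 0, accumulation = 0.5,
                        grid = sim_grid(61, 30, 20, 2700, 1))
  H <- dim(sc$stack)[2]; W <- dim(sc$stack)[3]
  col_lo <- round(12 / sc$pixel_size) + sc$truth$margin_px
  col_hi <- round(18 / sc$pixel_size) + sc$truth$margin_px
  rows <- (sc$truth$fibre_row - 3):(sc$truth$fibre_row + 3)
  roi <- matrix(FALSE, H, W); roi[rows, col_lo:col_hi] <- TRUE
  ctl <- matrix(FALSE, H, W); ctl[rows, 20:(col_lo - 40)] <- TRUE
  bg <- matrix(FALSE, H, W); bg[2:6, 2:6] <- TRUE
  times <- (seq_len(dim(sc$stack)[1]) - 1) * sc$dt
  tr <- recruitment_trace(sc$stack, roi, ctl, bg, times)
  expect_equal(mean(tr$normalized[times <= 900]), 1, tolerance = 0.01)
  # configured amplitude 0.5: plateau at 1.5-fold
  expect_equal(max(tr$normalized), 1.5, tolerance = 0.075)
})

test_that("adhesion segmentation applies the minimum-area rule", {
  ps <- 0.1
  img <- matrix(0, 80, 80)
  expect_equal(nrow(segment_adhesions(img, ps)$table), 0)

  # three square patches of 20, 40 and 100 px at 0.1 um/px:
  # areas 0.2, 0.4 and 1.0 um^2; the rule excludes strictly < 0.4
  img[10:13, 10:14] <- 1            # 20 px = 0.2 um^2
  img[30:34, 30:37] <- 1            # 40 px = 0.4 um^2
  img[60:69, 60:69] <- 1            # 100 px = 1.0 um^2
  seg <- segment_adhesions(img, ps, tophat_radius = 0)
  expect_equal(nrow(seg$table), 2)
  expect_equal(sort(seg$table$area), c(0.4, 1.0))

  # filtering is idempotent: re-running on the kept mask changes nothing
  seg2 <- segment_adhesions((seg$mask > 0) * 1, ps, tophat_radius = 0)
  expect_equal(nrow(seg2$table), 2)
  expect_equal(sort(seg2$table$area), sort(seg$table$area))
})

test_that("seeded elliptical adhesions are found with sub-pixel centroids", {
  sc <- gen_adhesion_movie(n_adhesions = 10, seed = 7, noise = TRUE)
  seg <- segment_adhesions(sc$stack[1, , ], sc$pixel_size)
  expect_equal(nrow(seg$table), 10)
  # match centroids to the generator's ground truth
  tru <- sc$truth$centres
  for (i in seq_len(nrow(tru))) {
    d <- sqrt((seg$table$cx / sc$pixel_size - tru[i, "x"])^2 +
                (seg$table$cy / sc$pixel_size - tru[i, "y"])^2)
    expect_lt(min(d), 1)
  }
})

test_that("adhesion dynamics apply the >10% increase rule", {
  sc <- gen_adhesion_movie(n_adhesions = 10, risers = c(2, 3, 5, 7, 8, 10),
                           rise_factor = 1.3, seed = 9, noise = FALSE)
  nf <- dim(sc$stack)[1]
  segs <- lapply(seq_len(nf), function(f)
    segment_adhesions(sc$stack[f, , ], sc$pixel_size))
  imgs <- lapply(seq_len(nf), function(f) sc$stack[f, , ])
  times <- sc$truth$times
  pre <- max(which(times <= 900))
  act <- which(times > 900 & times <= 1800)
  dyn <- adhesion_dynamics(segs, imgs, NULL, pre, act)
  # count stays constant
  expect_true(all(dyn$counts == 10))
  expect_equal(dyn$fraction_intensity_increased, 0.6)

  # 1.05x rise is below the 10% rule; 1.2x is above
  sc2 <- gen_adhesion_movie(n_adhesions = 6, risers = c(1, 2),
                            rise_factor = 1.05, seed = 10, noise = FALSE)
  segs2 <- lapply(seq_len(nf), function(f)
    segment_adhesions(sc2$stack[f, , ], sc2$pixel_size))
  imgs2 <- lapply(seq_len(nf), function(f) sc2$stack[f, , ])
  dyn2 <- adhesion_dynamics(segs2, imgs2, NULL, pre, act)
  expect_equal(dyn2$fraction_intensity_increased, 0)
  sc3 <- gen_adhesion_movie(n_adhesions = 6, risers = c(1, 2),
                            rise_factor = 1.2, seed = 10, noise = FALSE)
  segs3 <- lapply(seq_len(nf), function(f)
    segment_adhesions(sc3$stack[f, , ], sc3$pixel_size))
  imgs3 <- lapply(seq_len(nf), function(f) sc3$stack[f, , ])
  dyn3 <- adhesion_dynamics(segs3, imgs3, NULL, pre, act)
  expect_equal(dyn3$fraction_intensity_increased, 2 / 6)
})

test_that("puncta tracking recovers imposed velocities and discontinuities", {
  # kymograph of drifting puncta with uniform slope
  np <- 8; nt <- 40
  dx <- 0.1; dt <- 20
  slope_px <- 0.15                     # px per frame
  x0 <- seq(10, 80, length.out = np)
  vals <- matrix(0, 100, nt)
  for (t in seq_len(nt))
    for (p in seq_len(np))
      vals[, t] <- vals[, t] + exp(-((1:100) - x0[p] -
                                       slope_px * (t - 1))^2 / 4)
  k <- kymograph(vals, dx, dt, "intensity")
  res <- puncta_tracks(k, activation_window = c(0, 1e9), prominence = 1)
  expect_gte(length(res$tracks), np - 1)
  v_exp <- slope_px * dx / dt
  expect_lt(max(abs(res$velocity - v_exp), na.rm = TRUE), 0.05 * v_exp +
              1e-7)

  # stationary puncta: velocities at the noise floor
  vals0 <- matrix(0, 100, nt)
  for (t in seq_len(nt))
    for (p in seq_len(np))
      vals0[, t] <- vals0[, t] + exp(-((1:100) - x0[p])^2 / 4)
  res0 <- puncta_tracks(kymograph(vals0, dx, dt, "intensity"),
                        activation_window = c(0, 1e9), prominence = 1)
  expect_lt(max(abs(res0$velocity), na.rm = TRUE), 1e-6)

  # an imposed velocity discontinuity between adjacent puncta is flagged
  # by the neighbour-difference series
  vals2 <- matrix(0, 100, nt)
  vmap <- ifelse(x0 < 45, 0.3, 0)      # left half moves, right half static
  for (t in seq_len(nt))
    for (p in seq_len(np))
      vals2[, t] <- vals2[, t] + exp(-((1:100) - x0[p] -
                                         vmap[p] * (t - 1))^2 / 4)
  res2 <- puncta_tracks(kymograph(vals2, dx, dt, "intensity"),
                        activation_window = c(0, 1e9), prominence = 1)
  nd <- res2$neighbor_diff
  imax <- which.max(abs(nd$dv))
  # the flagged pair brackets the imposed break at x = 45 px
  p_a <- res2$tracks[[nd$track_a[imax]]]$pos_px[1]
  p_b <- res2$tracks[[nd$track_b[imax]]]$pos_px[1]
  expect_true(p_a < 50 && p_b > 40)
  expect_gt(abs(nd$dv[imax]), 0.5 * 0.3 * dx / dt)
})

test_that("displacement reversal flags static kymographs and splits groups", {
  # static kymograph: no displaceable ridge, record flagged
  vals <- matrix(rep(exp(-((1:200) - 100)^2 / 9), 30), 200, 30)
  k <- kymograph(vals, 0.1, 100, "intensity")
  rec <- displacement_reversal(k, c(0, 5), t_on = 900, t_off = 1800,
                               offset = 5)
  expect_true(rec$flagged)

  # two-group clustering of reversal fractions
  set.seed(3)
  r <- c(rnorm(10, 0.8, 0.05), rnorm(10, 0.25, 0.05))
  rec2 <- data.frame(r = r)
  cl <- cluster_reversal(rec2)
  expect_false(cl$degenerate)
  expect_equal(sort(cl$means), c(0.25, 0.8), tolerance = 0.15)
  truth <- rep(c(2L, 1L), each = 10)
  agree <- mean(cl$assignment == truth)
  expect_true(agree == 1 || agree == 0)   # labels up to permutation

  # order invariance
  perm <- sample(20)
  cl2 <- cluster_reversal(data.frame(r = r[perm]))
  expect_equal(sort(cl2$means), sort(cl$means))
  expect_equal(cl2$assignment, cl$assignment[perm])

  # degenerate input collapses to one group with a warning
  expect_warning(cl3 <- cluster_reversal(data.frame(r = rep(0.5, 8))),
                 "degenerate")
  expect_true(cl3$degenerate)
  expect_error(cluster_reversal(data.frame(r = c(0.1, 0.2))), "at least 6")
})

test_that("elastic scenes reverse displacement; fluid scenes do not", {
  # two scenes per condition, features on both flanks
  revs <- function(set, seeds) do.call(rbind, lapply(seeds, function(s) {
    sc <- reference_scenes(seed = s, which = set)[[set]]
    path <- fibremech:::fibre_scene_path(sc)
    k <- extract_kymograph(sc$stack, path, pixel_size = sc$pixel_size,
                           dt = sc$dt)
    rbind(displacement_reversal(k, c(25, 35), offset = 5),
          displacement_reversal(k, c(25, 35), offset = -5))
  }))
  r1 <- revs("R1", c(501, 502))
  r2 <- revs("R2", c(501, 502))
  expect_gt(mean(r1$d_act), 2)
  expect_gt(mean(r1$r, na.rm = TRUE), mean(r2$r, na.rm = TRUE) + 0.4)
  expect_lt(abs(mean(r2$r, na.rm = TRUE)), 0.25)
})
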