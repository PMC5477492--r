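#' Particle image velocimetry on bead images
#'
#' Windowed normalized cross-correlation between a reference and a deformed
#' bead image, with sub-pixel Gaussian peak interpolation, outlier removal
#' by the normalized-median test, and interpolation of removed/masked
#' vectors. The displacement field is returned on a regular physical grid
#' (default 0.86 um spacing).
#'
#' @param img_ref,img_def matrices (same shape), reference and deformed bead
#'   images.
#' @param pixel_size physical pixel pitch (um).
#' @param grid_spacing output grid spacing (um); default 0.86.
#' @param window interrogation window size in px (default 32).
#' @param overlap window overlap fraction (default 0.5).
#' @param search extra search margin in px for the correlation (default 8).
#' @param passes number of window-deformation passes (>= 1). Passes after
#'   the first warp the deformed image back by the current field and
#'   correlate the residual shifts, which removes the attenuation and
#'   broadening caused by displacement gradients inside the window.
#' @return a `"displacement"` [vector_field_2d()] in um.
#' @export
piv_beads <- function(img_ref, img_def, pixel_size,
                      grid_spacing = 0.86, window = 32, overlap = 0.5,
                      search = 8, passes = 3) {
  stopifnot(identical(dim(img_ref), dim(img_def)), pixel_size > 0,
            passes >= 1)
  H <- nrow(img_ref); W <- ncol(img_ref)
  field <- piv_pass(img_ref, img_def, pixel_size, grid_spacing, window,
                    overlap, search)
  if (max(abs(img_ref - img_def)) == 0) {
    field$vx[] <- 0; field$vy[] <- 0
    return(field)
  }
  for (p in seq_len(passes - 1)) {
    # smooth the predictor (its noise would otherwise accumulate), warp the
    # deformed image back by it, and re-measure the residual shifts
    pred <- field
    pred$vx <- box3_smooth(pred$vx)
    pred$vy <- box3_smooth(pred$vy)
    px <- pred$origin[1] + (seq_len(ncol(pred$vx)) - 1) * pred$spacing
    py <- pred$origin[2] + (seq_len(nrow(pred$vx)) - 1) * pred$spacing
    ux_full <- bilinear_grid(px / pixel_size + 1, py / pixel_size + 1,
                             pred$vx / pixel_size, seq_len(W), seq_len(H))
    uy_full <- bilinear_grid(px / pixel_size + 1, py / pixel_size + 1,
                             pred$vy / pixel_size, seq_len(W), seq_len(H))
    # sample the deformed image at x + u: beads move back to reference spots
    def_w <- warp_image(img_def, ux_full, uy_full)
    res <- piv_pass(img_ref, def_w, pixel_size, grid_spacing, window,
                    overlap, max(3, ceiling(search / 2)))
    field$vx <- pred$vx + res$vx
    field$vy <- pred$vy + res$vy
  }
  field
}

box3_smooth <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1, 1:(nr - 1)), ]; dn <- m[c(2:nr, nr), ]
  acc <- (up + m + dn)
  lf <- acc[, c(1, 1:(nc - 1))]; rt <- acc[, c(2:nc, nc)]
  (lf + acc + rt) / 9
}

piv_pass <- function(img_ref, img_def, pixel_size, grid_spacing, window,
                     overlap, search) {
  H <- nrow(img_ref); W <- ncol(img_ref)
  step <- max(4L, as.integer(round(window * (1 - overlap))))
  half <- window %/% 2
  cy <- seq(half + 1, H - half, by = step)
  cx <- seq(half + 1, W - half, by = step)
  if (length(cy) < 2 || length(cx) < 2)
    stop("images too small for the interrogation window", call. = FALSE)

  dxm <- matrix(NA_real_, length(cy), length(cx))
  dym <- matrix(NA_real_, length(cy), length(cx))
  pad <- search
  for (iy in seq_along(cy)) {
    for (ix in seq_along(cx)) {
      y0 <- cy[iy] - half; x0 <- cx[ix] - half
      ref <- img_ref[y0:(y0 + window - 1), x0:(x0 + window - 1)]
      yy0 <- max(1, y0 - pad); xx0 <- max(1, x0 - pad)
      yy1 <- min(H, y0 + window - 1 + pad); xx1 <- min(W, x0 + window - 1 + pad)
      def <- img_def[yy0:yy1, xx0:xx1]
      if (sd(ref) < 1e-12 || sd(def) < 1e-12) next    # textureless: mask
      cc <- xcorr2_norm(def, ref)
      pk <- subpixel_peak(cc)
      # displacement of the deformed image relative to the reference window
      dym[iy, ix] <- (pk[1] - 1) + (yy0 - y0)
      dxm[iy, ix] <- (pk[2] - 1) + (xx0 - x0)
    }
  }
  # normalized-median outlier test (3x3 neighbourhoods)
  for (comp in c("dxm", "dym")) {
    m <- get(comp)
    out <- nmt_outliers(dxm, dym)
    m[out] <- NA
    assign(comp, m)
  }
  dxm <- fill_na_bilinear(dxm)
  dym <- fill_na_bilinear(dym)

  # resample to the requested physical grid
  px <- (cx - 1) * pixel_size
  py <- (cy - 1) * pixel_size
  gx <- seq(min(px), max(px), by = grid_spacing)
  gy <- seq(min(py), max(py), by = grid_spacing)
  ux <- bilinear_grid(px, py, dxm * pixel_size, gx, gy)
  uy <- bilinear_grid(px, py, dym * pixel_size, gx, gy)
  vector_field_2d(ux, uy, grid_spacing, "displacement",
                  origin = c(min(px), min(py)))
}

# normalized cross-correlation of template tpl within image img (valid
# mode): per-shift zero-mean unit-variance normalization via box sums
xcorr2_norm <- function(img, tpl) {
  tpl <- tpl - mean(tpl)
  H <- nrow(img); W <- ncol(img)
  h <- nrow(tpl); w <- ncol(tpl)
  n <- h * w
  P1 <- matrix(0, H, W); P1[1:h, 1:w] <- tpl[h:1, w:1]
  Ft <- fft(P1)
  raw <- Re(fft(fft(img) * Ft, inverse = TRUE)) / (H * W)
  box <- matrix(0, H, W); box[1:h, 1:w] <- 1
  Fb <- fft(box)
  s1 <- Re(fft(fft(img) * Fb, inverse = TRUE)) / (H * W)      # window sums
  s2 <- Re(fft(fft(img^2) * Fb, inverse = TRUE)) / (H * W)
  denom <- sqrt(pmax(s2 - s1^2 / n, 0) * sum(tpl^2))
  cc <- raw / pmax(denom, 1e-8 * max(denom))
  cc[h:H, w:W, drop = FALSE]   # valid region; [1,1] = zero offset
}

# sub-pixel interpolation around the correlation peak: least-squares
# log-Gaussian (paraboloid) fit on the 3x3 neighbourhood, with a 3-point
# fit fallback at borders or for non-positive neighbourhoods
subpixel_peak <- function(cc) {
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  r <- pk[1]; c <- pk[2]
  if (r > 1 && r < nrow(cc) && c > 1 && c < ncol(cc)) {
    nb <- cc[(r - 1):(r + 1), (c - 1):(c + 1)]
    if (all(nb > 0)) {
      z <- log(nb)
      dx <- rep(-1:1, each = 3); dy <- rep(-1:1, 3)   # col-major: dy fast
      X <- cbind(1, dx, dy, dx^2, dy^2, dx * dy)
      b <- qr.coef(qr(X), as.vector(z))
      den <- 4 * b[4] * b[5] - b[6]^2
      if (is.finite(den) && abs(den) > 1e-12 && b[4] < 0 && b[5] < 0) {
        sx <- (b[6] * b[3] - 2 * b[5] * b[2]) / den
        sy <- (b[6] * b[2] - 2 * b[4] * b[3]) / den
        if (abs(sx) <= 1 && abs(sy) <= 1)
          return(c(r + sy, c + sx))
      }
    }
  }
  refine <- function(cm, c0, cp) {
    if (cm > 0 && c0 > 0 && cp > 0) {       # 3-point Gaussian fit
      lm <- log(cm); l0 <- log(c0); lp <- log(cp)
      den <- lm - 2 * l0 + lp
      if (abs(den) < 1e-12) return(0)
      return(max(-1, min(1, (lm - lp) / (2 * den))))
    }
    den <- cm - 2 * c0 + cp                  # parabolic fallback
    if (abs(den) < 1e-12) return(0)
    max(-1, min(1, (cm - cp) / (2 * den)))
  }
  dy <- if (r > 1 && r < nrow(cc))
    refine(cc[r - 1, c], cc[r, c], cc[r + 1, c]) else 0
  dx <- if (c > 1 && c < ncol(cc))
    refine(cc[r, c - 1], cc[r, c], cc[r, c + 1]) else 0
  c(r + dy, c + dx)
}

# Westerweel-style normalized median test on both components jointly
nmt_outliers <- function(dx, dy, thresh = 2, eps = 0.1) {
  bad <- matrix(FALSE, nrow(dx), ncol(dx))
  for (iy in seq_len(nrow(dx))) {
    for (ix in seq_len(ncol(dx))) {
      if (is.na(dx[iy, ix])) next
      ys <- max(1, iy - 1):min(nrow(dx), iy + 1)
      xs <- max(1, ix - 1):min(ncol(dx), ix + 1)
      for (m in list(dx, dy)) {
        nb <- m[ys, xs]
        nb <- nb[!is.na(nb)]
        nb <- nb[-which.min(abs(nb - m[iy, ix]))[1]]  # drop self (closest)
        if (length(nb) < 3) next
        med <- median(nb)
        res <- median(abs(nb - med))
        if (abs(m[iy, ix] - med) / (res + eps) > thresh) bad[iy, ix] <- TRUE
      }
    }
  }
  bad
}

fill_na_bilinear <- function(m) {
  if (!anyNA(m)) return(m)
  yy <- row(m); xx <- col(m)
  ok <- !is.na(m)
  if (sum(ok) < 4) stop("too few valid PIV vectors to interpolate",
                        call. = FALSE)
  bad <- which(!ok)
  # inverse-distance weighting from valid neighbours (simple, robust fill)
  for (i in bad) {
    d2 <- (yy[ok] - yy[i])^2 + (xx[ok] - xx[i])^2
    w <- 1 / (d2 + 1e-12)
    m[i] <- sum(w * m[ok]) / sum(w)
  }
  m
}

# bilinear resample of matrix z sampled at (px, py) onto grid (gx, gy)
bilinear_grid <- function(px, py, z, gx, gy) {
  zi <- apply(z, 1, function(rowv) approx(px, rowv, xout = gx, rule = 2)$y)
  # zi is now length(gx) x length(py); interpolate along y
  out <- apply(zi, 1, function(colv) approx(py, colv, xout = gy, rule = 2)$y)
  out
}
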