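#' Fibre path in image coordinates
#'
#' An ordered polyline along a stress fibre, in pixel coordinates
#' (`x` = column, `y` = row, 1-based), resampled to 1-px arc-length steps
#' with unit tangents.
#'
#' @param xy n x 2 matrix of polyline vertices (px).
#' @return object of class `"fibre_path"`: `points` (resampled, m x 2),
#'   `tangent` (m x 2 unit vectors), `arc` (arc length per sample, px).
#' @export
fibre_path <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 2)
  seg <- diff(xy)
  len <- sqrt(rowSums(seg^2))
  if (any(len < 1e-9)) stop("degenerate path segment", call. = FALSE)
  s <- c(0, cumsum(len))
  arc <- seq(0, sum(len), by = 1)
  px <- approx(s, xy[, 1], xout = arc)$y
  py <- approx(s, xy[, 2], xout = arc)$y
  # tangents by central differences along the resampled path
  tx <- mid_diff(px); ty <- mid_diff(py)
  nrm <- sqrt(tx^2 + ty^2)
  structure(list(points = cbind(x = px, y = py),
                 tangent = cbind(tx / nrm, ty / nrm), arc = arc),
            class = "fibre_path")
}

#' Extract an intensity kymograph along a fibre
#'
#' Samples the stack along the path at 1-px arc-length steps, averaging over
#' `width` px perpendicular to the local tangent (bilinear interpolation;
#' discrete `width`-sample stencil centred on the path). Rows are arc
#' length, columns time.
#'
#' @param stack array `[frame, row, col]`.
#' @param path a [fibre_path()] (or n x 2 polyline matrix).
#' @param width perpendicular averaging width in px (default 9).
#' @param pixel_size um per px.
#' @param dt s per frame.
#' @return an intensity [kymograph()] with `dx = pixel_size`, `dt = dt`.
#' @export
extract_kymograph <- function(stack, path, width = 9, pixel_size = 0.108,
                              dt = 20) {
  if (!inherits(path, "fibre_path")) path <- fibre_path(path)
  stopifnot(length(dim(stack)) == 3)
  H <- dim(stack)[2]; W <- dim(stack)[3]
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = width)
  # normals: rotate tangent by 90 degrees
  nx <- -path$tangent[, 2]; ny <- path$tangent[, 1]
  xs <- outer(path$points[, "x"], rep(1, width)) + outer(nx, offs)
  ys <- outer(path$points[, "y"], rep(1, width)) + outer(ny, offs)
  if (any(xs < 1 | xs > W | ys < 1 | ys > H)) {
    warning("kymograph path (with width) clipped to image bounds")
    xs <- pmin(pmax(xs, 1), W); ys <- pmin(pmax(ys, 1), H)
  }
  nf <- dim(stack)[1]
  vals <- vapply(seq_len(nf), function(f) {
    img <- stack[f, , ]
    rowMeans(matrix(bilinear_at(img, ys, xs), nrow(xs), ncol(xs)))
  }, numeric(nrow(xs)))
  kymograph(vals, dx = pixel_size, dt = dt, kind = "intensity",
            meta = list(width = width))
}

#' Project a flow field onto a fibre to a signed-speed kymograph
#'
#' Samples the flow at each path point (averaged over `width` px
#' perpendicular to the tangent) and projects it onto the local unit
#' tangent. Positive speed points toward increasing arc length.
#'
#' @param flow a [optical_flow()] result (px/frame).
#' @param path a [fibre_path()] or polyline matrix.
#' @param width perpendicular averaging width (px).
#' @param pixel_size um per px.
#' @param dt s per frame.
#' @return a signed-speed [kymograph()] in um/s.
#' @export
project_flow <- function(flow, path, width = 9, pixel_size = 0.108,
                         dt = 20) {
  if (!inherits(path, "fibre_path")) path <- fibre_path(path)
  stopifnot(inherits(flow, "flow_field"))
  H <- dim(flow$vx)[2]; W <- dim(flow$vx)[3]
  offs <- seq(-(width - 1) / 2, (width - 1) / 2, length.out = width)
  nx <- -path$tangent[, 2]; ny <- path$tangent[, 1]
  xs <- pmin(pmax(outer(path$points[, "x"], rep(1, width)) +
                    outer(nx, offs), 1), W)
  ys <- pmin(pmax(outer(path$points[, "y"], rep(1, width)) +
                    outer(ny, offs), 1), H)
  np <- dim(flow$vx)[1]
  vals <- vapply(seq_len(np), function(f) {
    fx <- rowMeans(matrix(bilinear_at(flow$vx[f, , ], ys, xs),
                          nrow(xs), ncol(xs)))
    fy <- rowMeans(matrix(bilinear_at(flow$vy[f, , ], ys, xs),
                          nrow(xs), ncol(xs)))
    fx * path$tangent[, 1] + fy * path$tangent[, 2]
  }, numeric(nrow(xs)))
  kymograph(vals * pixel_size / dt, dx = pixel_size, dt = dt,
            kind = "speed", meta = list(width = width))
}

# bilinear interpolation of img at fractional (row = Y, col = X)
bilinear_at <- function(img, Y, X) {
  nr <- nrow(img); nc <- ncol(img)
  Y <- pmin(pmax(Y, 1), nr); X <- pmin(pmax(X, 1), nc)
  y0 <- pmin(floor(Y), nr - 1); x0 <- pmin(floor(X), nc - 1)
  fy <- Y - y0; fx <- X - x0
  v00 <- img[cbind(as.vector(y0), as.vector(x0))]
  v01 <- img[cbind(as.vector(y0), as.vector(x0 + 1))]
  v10 <- img[cbind(as.vector(y0 + 1), as.vector(x0))]
  v11 <- img[cbind(as.vector(y0 + 1), as.vector(x0 + 1))]
  (1 - fy) * (1 - fx) * v00 + (1 - fy) * fx * v01 +
    fy * (1 - fx) * v10 + fy * fx * v11
}
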