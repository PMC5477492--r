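#' Kymograph container
#'
#' A space x time matrix sampled along a path, with physical calibration.
#' Rows index arc length (step `dx`), columns index time (step `dt`).
#' `kind` records whether entries are intensities (a.u.) or signed speeds
#' (um/s, positive toward increasing arc length).
#'
#' @param values numeric matrix, space x time.
#' @param dx spatial calibration (um per row).
#' @param dt temporal calibration (s per column).
#' @param kind `"intensity"` or `"speed"`.
#' @param meta optional list of provenance metadata.
#' @return object of class `"kymograph"`.
#' @export
kymograph <- function(values, dx, dt, kind = c("intensity", "speed"),
                      meta = list()) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    stop("kymograph values must be finite", call. = FALSE)
  if (dx <= 0 || dt <= 0)
    stop("dx and dt must be positive", call. = FALSE)
  structure(list(values = values, dx = dx, dt = dt, kind = kind, meta = meta),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph (%s): %d positions x %d frames, dx = %g um, dt = %g s\n",
              x$kind, nrow(x$values), ncol(x$values), x$dx, x$dt))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  zlim <- range(x$values)
  col <- if (x$kind == "speed") hcl.colors(64, "Blue-Red 3") else
    hcl.colors(64, "Grays", rev = TRUE)
  if (x$kind == "speed") zlim <- c(-1, 1) * max(abs(zlim))
  image(x = seq_len(ncol(x$values)) * x$dt / 60,
        y = seq_len(nrow(x$values)) * x$dx,
        z = t(x$values), col = col, zlim = zlim,
        xlab = "time (min)", ylab = "arc length (um)", ...)
  invisible(x)
}

# arc-length axis (um) and time axis (s) helpers
kymo_space <- function(k) (seq_len(nrow(k$values)) - 1) * k$dx
kymo_time <- function(k) (seq_len(ncol(k$values)) - 1) * k$dt
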