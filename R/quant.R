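#' Normalized local recruitment intensity trace
#'
#' Mean intensity of an activation ROI, background-subtracted, corrected for
#' photobleaching using a single-exponential fit to a control ROI, and
#' normalized so that the baseline-window mean is 1.
#'
#' @param stack array `[frame, row, col]`.
#' @param roi,control_roi,background_roi logical masks (row x col), mutually
#'   disjoint.
#' @param times frame times (s); default `0, dt, ...` with `dt = 20`.
#' @param baseline_window time window (s, length 2) defining the baseline;
#'   default first 15 min.
#' @return object of class `"intensity_trace"`: data.frame with columns
#'   `time`, `raw`, `control`, `corrected`, `normalized`.
#' @export
recruitment_trace <- function(stack, roi, control_roi, background_roi,
                              times = NULL, baseline_window = c(0, 900)) {
  stopifnot(length(dim(stack)) == 3)
  if (any(roi & control_roi) || any(roi & background_roi) ||
      any(control_roi & background_roi))
    stop("ROIs must be disjoint", call. = FALSE)
  nf <- dim(stack)[1]
  if (is.null(times)) times <- (seq_len(nf) - 1) * 20
  tr_roi <- vapply(seq_len(nf), function(f) mean(stack[f, , ][roi]),
                   numeric(1))
  tr_ctl <- vapply(seq_len(nf), function(f) mean(stack[f, , ][control_roi]),
                   numeric(1))
  tr_bg <- vapply(seq_len(nf), function(f)
    mean(stack[f, , ][background_roi]), numeric(1))
  roi_b <- tr_roi - tr_bg
  ctl_b <- tr_ctl - tr_bg
  # bleaching correction from the control curve
  fit <- lm(log(pmax(ctl_b, 1e-12)) ~ times)
  k <- coef(fit)[2]
  if (k >= 0) {
    warning("control ROI does not decay; skipping bleach correction")
    corr <- roi_b
  } else {
    bleach <- exp(k * (times - times[1]))
    corr <- roi_b / bleach
  }
  base <- times >= baseline_window[1] & times <= baseline_window[2]
  normalized <- corr / mean(corr[base])
  structure(data.frame(time = times, raw = tr_roi, control = tr_ctl,
                       corrected = corr, normalized = normalized),
            class = c("intensity_trace", "data.frame"))
}

#' Segment focal adhesions in a fluorescence image
#'
#' Background flattening by morphological top-hat, global Otsu threshold
#' (or a fixed threshold), connected-component labelling, and removal of
#' components smaller than `min_area`.
#'
#' @param img numeric matrix (row x col).
#' @param pixel_size um per px.
#' @param min_area minimum adhesion area (um^2), default 0.4; components
#'   strictly smaller are excluded.
#' @param threshold `"otsu"` or a numeric fixed threshold applied to the
#'   top-hat image.
#' @param tophat_radius structuring-element radius (px) for background
#'   flattening; 0 disables.
#' @return list with `table` (data.frame: `label`, `area` um^2, `cx`, `cy`
#'   um, `mean_intensity`) and `mask` (labelled integer matrix).
#' @export
segment_adhesions <- function(img, pixel_size, min_area = 0.4,
                              threshold = "otsu", tophat_radius = 15) {
  stopifnot(pixel_size > 0)
  work <- img
  if (tophat_radius > 0) {
    kern <- EBImage::makeBrush(2 * tophat_radius + 1, shape = "disc")
    work <- EBImage::whiteTopHat(img, kern)
  }
  rng <- range(work)
  if (diff(rng) < 1e-12)
    return(list(table = empty_adhesion_table(), mask = matrix(0L, nrow(img),
                                                              ncol(img))))
  scaled <- (work - rng[1]) / diff(rng)
  thr <- if (identical(threshold, "otsu"))
    EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  else (threshold - rng[1]) / diff(rng)
  bin <- scaled > thr
  lab <- EBImage::bwlabel(bin)
  n <- max(lab)
  if (n == 0)
    return(list(table = empty_adhesion_table(), mask = matrix(0L, nrow(img),
                                                              ncol(img))))
  px_area <- pixel_size^2
  rows <- lapply(seq_len(n), function(l) {
    sel <- lab == l
    area <- sum(sel) * px_area
    data.frame(label = l, area = area,
               cx = mean(col(img)[sel]) * pixel_size,
               cy = mean(row(img)[sel]) * pixel_size,
               mean_intensity = mean(img[sel]))
  })
  tab <- do.call(rbind, rows)
  keep <- tab$area >= min_area
  mask <- matrix(as.integer(lab), nrow(img), ncol(img))
  mask[!(mask %in% tab$label[keep])] <- 0L
  list(table = tab[keep, , drop = FALSE], mask = mask)
}

empty_adhesion_table <- function()
  data.frame(label = integer(0), area = numeric(0), cx = numeric(0),
             cy = numeric(0), mean_intensity = numeric(0))

#' Focal adhesion dynamics across an activation protocol
#'
#' Tracks adhesions across frames by mask overlap (>= 50% of the
#' pre-activation mask) and classifies each as increased in intensity or
#' traction stress if its maximum during activation exceeds its value
#' immediately before activation by more than 10%.
#'
#' @param segs list of [segment_adhesions()] results, one per frame.
#' @param stacks list of intensity images (one per frame) used for the
#'   intensity readout.
#' @param traction_maps optional list of traction-magnitude matrices (Pa)
#'   per frame; `NULL` skips the stress fractions.
#' @param pre_frame index of the frame immediately before activation.
#' @param activation_frames indices of the activation-phase frames.
#' @return list with `counts` (adhesions per frame),
#'   `fraction_intensity_increased`, `fraction_stress_increased` (NA if no
#'   traction maps) and `per_adhesion` data.frame.
#' @export
adhesion_dynamics <- function(segs, stacks, traction_maps = NULL,
                              pre_frame, activation_frames) {
  counts <- vapply(segs, function(s) nrow(s$table), integer(1))
  ref <- segs[[pre_frame]]
  labs <- ref$table$label
  per <- lapply(labs, function(l) {
    sel <- ref$mask == l
    a0 <- sum(sel)
    track_mean <- function(fi, imgs) {
      m <- segs[[fi]]$mask
      ov <- m[sel]
      ov <- ov[ov > 0]
      if (length(ov) == 0) return(NA_real_)
      cand <- as.integer(names(which.max(table(ov))))
      if (sum(m[sel] == cand) < 0.5 * a0) return(NA_real_)
      mean(imgs[[fi]][m == cand])
    }
    i_pre <- mean(stacks[[pre_frame]][sel])
    i_act <- vapply(activation_frames, track_mean, numeric(1), imgs = stacks)
    s_pre <- if (!is.null(traction_maps))
      mean(traction_maps[[pre_frame]][sel]) else NA_real_
    s_act <- if (!is.null(traction_maps))
      vapply(activation_frames, track_mean, numeric(1),
             imgs = traction_maps) else NA_real_
    data.frame(label = l,
               tracked = !all(is.na(i_act)),
               intensity_ratio = if (all(is.na(i_act))) NA_real_ else
                 max(i_act, na.rm = TRUE) / i_pre,
               stress_ratio = if (is.null(traction_maps) ||
                                  all(is.na(s_act))) NA_real_ else
                 max(s_act, na.rm = TRUE) / s_pre)
  })
  per <- do.call(rbind, per)
  ok <- per$tracked
  list(counts = counts,
       fraction_intensity_increased =
         mean(per$intensity_ratio[ok] > 1.10, na.rm = TRUE),
       fraction_stress_increased = if (is.null(traction_maps)) NA_real_ else
         mean(per$stress_ratio[ok] > 1.10, na.rm = TRUE),
       per_adhesion = per)
}

#' Track puncta in an intensity kymograph
#'
#' Detects local intensity peaks per time column, links them into tracks by
#' nearest-neighbour association within a gating radius, and estimates each
#' track's velocity by a least-squares line fit over the activation window.
#' Velocity differences between spatially adjacent tracks are reported;
#' abrupt neighbour differences mark sites of mechanical discontinuity.
#'
#' @param kymo an intensity [kymograph()] of punctate signal.
#' @param activation_window time window (s, length 2) for the velocity fit.
#' @param prominence peak threshold as a multiple of the kymograph noise
#'   level (MAD of the column-detrended signal); default 3.
#' @param gate linking gate (px/frame), default 3.
#' @param min_len minimum track length (frames), default 5.
#' @return list with `tracks` (list of data.frames `frame`, `pos_px`),
#'   `velocity` (um/s per track), `neighbor_diff` (data.frame of adjacent
#'   track pairs and their velocity difference).
#' @export
puncta_tracks <- function(kymo, activation_window = NULL, prominence = 3,
                          gate = 3, min_len = 5) {
  stopifnot(inherits(kymo, "kymograph"))
  V <- kymo$values
  nt <- ncol(V)
  ts <- kymo_time(kymo)
  if (is.null(activation_window)) activation_window <- range(ts)
  peaks_per_col <- lapply(seq_len(nt), function(j) {
    col <- V[, j]
    noise <- mad(diff(col)) / sqrt(2) + 1e-12
    p <- which(diff(sign(diff(col))) == -2) + 1
    p <- p[col[p] > median(col) + prominence * noise]
    # parabolic sub-pixel refinement of each peak
    vapply(p, function(i) {
      den <- col[i - 1] - 2 * col[i] + col[i + 1]
      if (abs(den) < 1e-12) return(as.numeric(i))
      i + min(0.5, max(-0.5, 0.5 * (col[i - 1] - col[i + 1]) / den))
    }, numeric(1))
  })
  # greedy nearest-neighbour linking
  tracks <- list()
  active <- list()
  for (j in seq_len(nt)) {
    pk <- peaks_per_col[[j]]
    used <- rep(FALSE, length(pk))
    if (length(active)) {
      keep <- logical(length(active))
      for (ai in seq_along(active)) {
        tr <- active[[ai]]
        last <- tr$pos_px[nrow(tr)]
        if (length(pk)) {
          d <- abs(pk - last)
          best <- which.min(d)
          if (d[best] <= gate && !used[best]) {
            active[[ai]] <- rbind(tr, data.frame(frame = j,
                                                 pos_px = pk[best]))
            used[best] <- TRUE
            keep[ai] <- TRUE
            next
          }
        }
        keep[ai] <- FALSE
        tracks[[length(tracks) + 1]] <- tr
      }
      active <- active[keep]
    }
    for (b in which(!used))
      active[[length(active) + 1]] <- data.frame(frame = j,
                                                 pos_px = pk[b])
  }
  tracks <- c(tracks, active)
  tracks <- Filter(function(tr) nrow(tr) >= min_len, tracks)

  vel <- vapply(tracks, function(tr) {
    tt <- ts[tr$frame]
    sel <- tt >= activation_window[1] & tt <= activation_window[2]
    if (sum(sel) < 3) return(NA_real_)
    unname(coef(lm(tr$pos_px[sel] * kymo$dx ~ tt[sel]))[2])
  }, numeric(1))

  pos0 <- vapply(tracks, function(tr) tr$pos_px[1], numeric(1))
  ord <- order(pos0)
  nd <- if (length(ord) >= 2)
    data.frame(track_a = ord[-length(ord)], track_b = ord[-1],
               dv = diff(vel[ord]))
  else data.frame(track_a = integer(0), track_b = integer(0),
                  dv = numeric(0))
  list(tracks = tracks, velocity = vel, neighbor_diff = nd)
}

#' Displacement reversal of a tracked kymograph feature
#'
#' Emulates the manual displacement measurement: a punctum ridge located at
#' a given offset from the activation-zone edge immediately before
#' activation is tracked through the kymograph; its displacement after the
#' activation phase (`d_act`) and after the relaxation phase (`d_rel`) are
#' reported together with the reversal fraction
#' `r = (d_act - d_rel)/d_act`. The ridge's baseline drift (estimated over
#' the pre-activation window) is extrapolated and subtracted, so the
#' reported displacements isolate the activation-induced motion from any
#' constant retrograde flow.
#'
#' @param kymo an intensity [kymograph()].
#' @param activation_region arc-length interval (um, length 2) of the
#'   activation zone along the path.
#' @param t_on,t_off activation switch times (s).
#' @param offset distance from the activation-zone edge at which the
#'   tracked feature starts (um); default 5. Positive offsets track on the
#'   far (increasing-arc) side, negative on the near side.
#' @param gate maximum tracked shift per frame (px); must exceed the
#'   fastest coherent motion (the recoil immediately after switch-off).
#' @param relax_window relaxation duration after `t_off` (s).
#' @return one-row data.frame (`d_act`, `d_rel`, `r`, `flagged`).
#' @export
displacement_reversal <- function(kymo, activation_region, t_on = 900,
                                  t_off = 1800, offset = 5, gate = 15,
                                  relax_window = 900) {
  stopifnot(inherits(kymo, "kymograph"))
  ts <- kymo_time(kymo)
  xs <- kymo_space(kymo)
  edge <- if (offset >= 0) activation_region[2] else activation_region[1]
  x_target <- edge + offset
  j_on <- max(which(ts <= t_on))
  j_off <- max(which(ts <= t_off))
  j_rel <- max(which(ts <= min(t_off + relax_window, max(ts))))

  # locate the ridge nearest the target position just before activation
  col <- kymo$values[, j_on]
  pk <- which(diff(sign(diff(col))) == -2) + 1
  if (length(pk) == 0)
    return(data.frame(d_act = 0, d_rel = 0, r = NA_real_, flagged = TRUE))
  i0 <- pk[which.min(abs(xs[pk] - x_target))]
  if (abs(xs[i0] - x_target) > 2.5)
    return(data.frame(d_act = 0, d_rel = 0, r = NA_real_, flagged = TRUE))

  # follow the local intensity pattern column-to-column by normalized
  # correlation over integer shifts (parabolic sub-pixel refinement); this
  # stays locked through the fast coherent recoil right after switch-off,
  # which can exceed the spacing between neighbouring puncta per frame
  half_win <- max(8L, round(1.2 / kymo$dx))
  track_from <- function(jstart, istart, jend, dir = 1L) {
    n <- nrow(kymo$values)
    pos <- numeric(abs(jend - jstart) + 1)
    pos[1] <- istart
    cur <- istart
    idx <- 2
    for (j in seq(jstart + dir, jend, by = dir)) {
      i0 <- round(cur)
      lo <- max(1, i0 - half_win); hi <- min(n, i0 + half_win)
      tpl <- kymo$values[lo:hi, j - dir]
      tpl <- tpl - mean(tpl)
      shifts <- -gate:gate
      sc <- vapply(shifts, function(s) {
        lo2 <- lo + s; hi2 <- hi + s
        if (lo2 < 1 || hi2 > n) return(-Inf)
        seg <- kymo$values[lo2:hi2, j]
        seg <- seg - mean(seg)
        den <- sqrt(sum(tpl^2) * sum(seg^2))
        if (den < 1e-12) return(-Inf)
        sum(tpl * seg) / den
      }, numeric(1))
      b <- which.max(sc)
      sh <- shifts[b]
      if (b > 1 && b < length(shifts) && all(is.finite(sc[(b - 1):(b + 1)]))) {
        den <- sc[b - 1] - 2 * sc[b] + sc[b + 1]
        if (abs(den) > 1e-12)
          sh <- sh + min(0.5, max(-0.5, 0.5 * (sc[b - 1] - sc[b + 1]) / den))
      }
      cur <- cur + sh
      # snap to the nearest intensity peak: the correlation keeps lock on
      # the moving pattern, the peak pins the material punctum itself
      i1 <- round(cur)
      lo <- max(2, i1 - 4); hi <- min(n - 1, i1 + 4)
      seg <- kymo$values[lo:hi, j]
      pk2 <- which(diff(sign(diff(seg))) == -2) + 1
      if (length(pk2)) {
        cand <- lo + pk2 - 1
        ip <- cand[which.min(abs(cand - cur))]
        den <- kymo$values[ip - 1, j] - 2 * kymo$values[ip, j] +
          kymo$values[ip + 1, j]
        frac <- if (abs(den) > 1e-12)
          min(0.5, max(-0.5, 0.5 * (kymo$values[ip - 1, j] -
                                      kymo$values[ip + 1, j]) / den))
        else 0
        cur <- ip + frac
      }
      pos[idx] <- cur
      idx <- idx + 1
    }
    pos
  }

  # backward over the baseline to estimate drift, forward to t_off + relax
  base_pos <- rev(track_from(j_on, i0, 1, dir = -1L))
  fwd_pos <- track_from(j_on, i0, j_rel, dir = 1L)
  tt_base <- ts[1:j_on]
  drift <- if (length(base_pos) >= 5)
    unname(coef(lm(base_pos ~ tt_base))[2]) else 0

  pos_at <- function(j) fwd_pos[j - j_on + 1]
  detr <- function(j) (pos_at(j) - pos_at(j_on) -
                         drift * (ts[j] - ts[j_on])) * kymo$dx
  d_act <- abs(detr(j_off))
  d_rel <- abs(detr(j_rel))
  lost <- anyNA(fwd_pos)
  if (d_act < 0.25)   # feature effectively static: reversal undefined
    return(data.frame(d_act = d_act, d_rel = d_rel, r = NA_real_,
                      flagged = TRUE))
  data.frame(d_act = d_act, d_rel = d_rel, r = (d_act - d_rel) / d_act,
             flagged = lost)
}

#' Two-group clustering of reversal fractions
#'
#' Deterministic 1D two-means clustering of reversal fractions `r`
#' (initialized at the min and max), separating strongly reversing fibres
#' from weakly reversing ones.
#'
#' @param records data.frame with a column `r` (e.g. rbind-ed
#'   [displacement_reversal()] rows).
#' @return list with `assignment` (1 = low-r group, 2 = high-r group),
#'   `means` (group means), `degenerate` flag.
#' @export
cluster_reversal <- function(records) {
  r <- records$r[!is.na(records$r)]
  if (length(r) < 6)
    stop("need at least 6 records with defined reversal fraction",
         call. = FALSE)
  if (diff(range(r)) < 1e-9) {
    warning("degenerate reversal fractions; single group")
    return(list(assignment = rep(1L, length(r)), means = mean(r),
                degenerate = TRUE))
  }
  c1 <- min(r); c2 <- max(r)
  for (it in 1:100) {
    a <- ifelse(abs(r - c1) <= abs(r - c2), 1L, 2L)
    n1 <- mean(r[a == 1L]); n2 <- mean(r[a == 2L])
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
    c1 <- n1; c2 <- n2
  }
  list(assignment = a, means = c(c1, c2), degenerate = FALSE)
}
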