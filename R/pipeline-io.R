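#' Read and write calibrated image stacks
#'
#' Stacks are stored as multi-page 16-bit TIFF plus a JSON sidecar
#' (`<path>.json`) carrying the physical calibration (`pixel_size` um,
#' `dt` s) and the count scale. A write-then-read round trip reproduces the
#' integer count array exactly.
#'
#' @param stack numeric array `[frame, row, col]` of non-negative counts.
#' @param path TIFF file path.
#' @param pixel_size um per px.
#' @param dt seconds per frame.
#' @return `write_image_stack`: invisibly, the sidecar path.
#' @export
write_image_stack <- function(stack, path, pixel_size, dt) {
  stopifnot(length(dim(stack)) == 3, all(stack >= 0))
  int_counts <- max(stack) <= 65535 &&
    max(abs(stack - round(stack))) < 1e-9
  # integer counts map exactly onto the 16-bit grid; other data are
  # quantized against their maximum
  scale <- if (int_counts) 65535 else max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[1]), function(f)
    stack[f, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(pixel_size = pixel_size, dt = dt,
                            scale = scale, integer_counts = int_counts,
                            frames = dim(stack)[1]),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_image_stack
#' @return `load_image_stack`: list with `stack` (array, counts),
#'   `pixel_size`, `dt`.
#' @export
load_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing calibration sidecar ", sidecar,
         "; image stacks need pixel_size and dt", call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  stack <- array(0, c(length(pages), H, W))
  for (f in seq_along(pages))
    stack[f, , ] <- round(pages[[f]] * 65535) / 65535 * meta$scale
  if (isTRUE(meta$integer_counts)) stack <- round(stack)
  list(stack = stack, pixel_size = meta$pixel_size, dt = meta$dt)
}

#' Save or load a kymograph as CSV with a metadata header
#'
#' @param kymo a [kymograph()].
#' @param path CSV path.
#' @export
write_kymograph_csv <- function(kymo, path) {
  con <- file(path, "w")
  writeLines(sprintf("# dx_um=%.10g dt_s=%.10g kind=%s", kymo$dx, kymo$dt,
                     kymo$kind), con)
  write.table(kymo$values, con, sep = ",", row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_kymograph_csv
#' @export
read_kymograph_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "dx_um=([0-9.eE+-]+) dt_s=([0-9.eE+-]+) kind=(\\w+)", hdr))[[1]]
  vals <- as.matrix(read.csv(path, skip = 1, header = FALSE))
  dimnames(vals) <- NULL
  kymograph(vals, dx = as.numeric(m[2]), dt = as.numeric(m[3]),
            kind = m[4])
}

#' Pipeline configuration
#'
#' Validates a configuration list (or JSON file) for [run_pipeline()].
#' Recognized blocks: `seed` (integer), `outdir`, `scene`
#' (`set` = "R1"/"R2" plus [gen_fibre_movie()] overrides), `flow`
#' (`smoothness`, `method`), `fit` (`n_starts`, `maxit`, `n_nodes`,
#' `dt_step`, `noise`). Unknown keys are rejected before any stage runs.
#'
#' @param config list or path to a JSON file.
#' @return validated config (class `"pipeline_config"`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  known <- c("seed", "outdir", "scene", "flow", "fit")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$outdir)) stop("config$outdir is required",
                                   call. = FALSE)
  config$scene <- config$scene %||% list()
  config$scene$set <- config$scene$set %||% "R1"
  stopifnot(config$scene$set %in% c("R1", "R2"))
  config$flow <- config$flow %||% list()
  config$fit <- config$fit %||% list()
  structure(config, class = "pipeline_config")
}

#' Run the synthetic analysis pipeline end to end
#'
#' Chains the stages of the study workflow on synthetic data: generate the
#' reference fibre scene, estimate dense flow, project it onto the fibre to
#' a kymograph, and fit the 1D continuum model to recover the viscoelastic
#' relaxation time. Every output file is listed in a manifest with md5
#' hashes; rerunning with an identical config and seed reproduces the
#' hashes.
#'
#' @param config a [pipeline_config()] (or list/path coercible to one).
#' @return the manifest (data.frame `file`, `md5`), invisibly; also written
#'   to `manifest.json` in `outdir` together with the fit summary.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(f) file.path(config$outdir, f)

  # stage: synth
  scene_args <- config$scene
  set <- scene_args$set
  scene_args$set <- NULL
  scene <- do.call(gen_fibre_movie,
                   c(list(params = reference_params(set),
                          protocol = reference_protocol(),
                          seed = config$seed), scene_args))
  write_image_stack(scene$stack, outfile("scene.tif"), scene$pixel_size,
                    scene$dt)

  # stage: flow + kymograph
  pre <- preprocess_stack(scene$stack)
  fl <- optical_flow(pre, smoothness = config$flow$smoothness %||% 20,
                     method = config$flow$method %||% "variational")
  path <- fibre_scene_path(scene)
  kymo <- project_flow(fl, path, pixel_size = scene$pixel_size,
                       dt = scene$dt)
  write_kymograph_csv(kymo, outfile("kymo_speed.csv"))

  # stage: fit
  fitcfg <- config$fit
  init <- model_params_1d(E = 300, eta = 5e5, gamma = 5e3, kM = 30,
                          dsigma = 800, L = reference_params(set)$L)
  set.seed(config$seed + 1L)
  fit <- fit_kymograph(kymo, reference_protocol(),
                       fixed_kM = reference_params(set)$kM, init = init,
                       n_starts = fitcfg$n_starts %||% 3,
                       maxit = fitcfg$maxit %||% 200,
                       n_nodes = fitcfg$n_nodes %||% 61,
                       dt_step = fitcfg$dt_step %||% 2)
  jsonlite::write_json(list(relaxation_time_s = fit$relaxation_time,
                            objective = fit$objective,
                            converged = fit$converged,
                            params = unclass(fit$params),
                            tau_a = fit$tau_a),
                       outfile("fit.json"), auto_unbox = TRUE, digits = NA)

  files <- c("scene.tif", "scene.tif.json", "kymo_speed.csv", "fit.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(outfile(files))),
                         row.names = NULL)
  jsonlite::write_json(list(seed = config$seed, scene = set,
                            manifest = manifest),
                       outfile("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

# straight path along the synthetic fibre, spanning the cell interior
fibre_scene_path <- function(scene) {
  W <- dim(scene$stack)[3]
  m <- scene$truth$margin_px
  fibre_path(cbind(c(m + 1, W - m), scene$truth$fibre_row))
}
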