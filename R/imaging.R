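# Voxelwise kinetic modelling: a 4-D dynamic image is fitted voxel by voxel
# within a mask to produce 3-D parametric maps (K1, k3, k5, HPI by default).
# NIfTI IO goes through RNifti; the frame schedule travels in a JSON sidecar.

#' 4-D dynamic PET image
#'
#' @param data 4-D numeric array in R's native order `(x, y, z, frame)`,
#'   kBq/mL.
#' @param schedule A [frame_schedule()]; its frame count must match the
#'   fourth dimension.
#' @param voxel_mm Voxel size in mm (length 3).
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity from `voxel_mm`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, schedule, voxel_mm = c(1, 1, 1),
                          affine = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4-D array (x, y, z, frame)")
  if (dim(data)[4] != n_frames(schedule))
    stop("frame count of the image does not match the schedule")
  if (any(!is.finite(data))) stop("image contains non-finite values")
  if (is.null(affine)) {
    affine <- diag(c(voxel_mm, 1))
  }
  structure(list(data = data, schedule = schedule,
                 voxel_mm = as.numeric(voxel_mm), affine = affine),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Read a 4-D dynamic image from NIfTI
#'
#' The frame schedule is taken from `schedule` or, if omitted, from the JSON
#' sidecar `<path without extension>.json` written by [write_maps()] /
#' [write_dynamic_image()].
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param schedule Optional [frame_schedule()] overriding the sidecar.
#' @return A [dynamic_image()].
#' @export
read_dynamic_image <- function(path, schedule = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(schedule)) {
    side <- sidecar_path(path)
    if (!file.exists(side))
      stop("no schedule given and no sidecar found at ", side)
    sj <- jsonlite::read_json(side, simplifyVector = TRUE)
    schedule <- frame_schedule(sj$frame_start_s, sj$frame_end_s)
  }
  arr <- array(as.numeric(img), dim = dim(img))
  dynamic_image(arr, schedule, voxel_mm = RNifti::pixdim(img)[1:3],
                affine = unclass(RNifti::xform(img)))
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' @rdname read_dynamic_image
#' @param img A [dynamic_image()] to write (stored as float32, with a JSON
#'   schedule sidecar).
#' @export
write_dynamic_image <- function(img, path) {
  stopifnot(inherits(img, "dynamic_image"))
  arr <- img$data
  attr(arr, "pixdim") <- c(img$voxel_mm, 1)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  jsonlite::write_json(
    list(frame_start_s = img$schedule$frame_start,
         frame_end_s = img$schedule$frame_end),
    sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Voxelwise kinetic model fitting
#'
#' Fits the chosen model independently to every masked voxel's TAC and
#' assembles 3-D parameter maps.  Each voxel uses a reduced multistart
#' (default 5 starts) seeded deterministically from the base seed plus the
#' voxel's linear index, so results do not depend on traversal order.
#' Because nine-parameter voxel fits are fragile at voxel noise levels, the
#' default voxelwise configuration freezes the slow ER dephosphorylation
#' rate at `k6 = 0.04` min^-1 (a typical tissue value); override via `cfg`.
#' Failed voxels -- those yielding no estimate at all -- are flagged in the
#' failure-code map (1 = degenerate TAC, 2 = every optimiser start errored)
#' and left missing in the parameter maps.  Voxels whose best run stopped at
#' the iteration cap still carry their best-found estimate; the `converged`
#' QC map records the optimiser status per voxel.
#'
#' @param img A [dynamic_image()].
#' @param mask 3-D logical/0-1 array matching the image grid.
#' @param a,pv Input [sampled_curve()]s.
#' @param model `"4C"` or `"3C"`.
#' @param params_to_map Parameter names to map (default K1, k3, k5, HPI).
#' @param cfg A [fit_config()]; the default voxelwise configuration is
#'   `fit_config(n_starts = 5, fixed = list(k6 = 0.04),
#'   include_static_frame = TRUE, max_iter = 150, tol = 1e-6)`.
#' @param base_seed Base seed for per-voxel start draws.
#' @return A `parametric_maps` object: `maps` (named list of 3-D arrays),
#'   `wrss`, `failure` (code array), `converged` (logical QC array),
#'   `mask`, `voxel_mm`, `affine`.
#' @export
fit_voxelwise <- function(img, mask, a, pv, model = c("4C", "3C"),
                          params_to_map = c("K1", "k3", "k5", "HPI"),
                          cfg = NULL, base_seed = 1L) {
  stopifnot(inherits(img, "dynamic_image"))
  model <- match.arg(model)
  d <- dim(img$data)[1:3]
  mask <- array(as.logical(mask), dim(as.array(mask)))
  if (!identical(dim(mask), d))
    stop("mask dimensions do not match the image grid")
  if (!any(mask)) stop("mask is empty")
  if (is.null(cfg)) {
    fixed <- if (model == "4C") list(k6 = 0.04) else list()
    cfg <- fit_config(n_starts = 5, fixed = fixed,
                      include_static_frame = TRUE, max_iter = 150,
                      tol = 1e-6)
  }
  bad <- setdiff(params_to_map,
                 names(unclass(if (model == "4C")
                   default_group_params("4C", "HCC")$mean
                   else default_group_params("3C", "HCC")$mean)))
  if (length(bad))
    stop("unknown parameters for this model: ", paste(bad, collapse = ", "))
  sched <- img$schedule
  ctx <- make_fit_context(sched, a, pv, model, cfg)
  per_voxel_w <- identical(cfg$weight_scheme, "inverse_variance")
  w <- if (per_voxel_w) NULL else tac_weights(cfg$weight_scheme, sched, NULL)
  maps <- stats::setNames(
    lapply(params_to_map, function(p) array(NA_real_, d)), params_to_map)
  wrss_map <- array(NA_real_, d)
  fail <- array(NA_integer_, d)
  fail[mask] <- 0L
  conv <- array(NA, d)
  vox <- which(mask)
  for (v in vox) {
    idx <- arrayInd(v, d)
    cv <- img$data[idx[1], idx[2], idx[3], ]
    if (all(cv == 0) || any(!is.finite(cv))) {
      fail[v] <- 1L
      next
    }
    vctx <- ctx
    vctx$cfg$seed <- as.integer((base_seed + v) %% .Machine$integer.max)
    wv <- if (per_voxel_w) tac_weights(cfg$weight_scheme, sched, cv) else w
    fit <- fit_tac_ctx(vctx, cv, wv)
    if (is.null(fit$theta_hat)) {
      fail[v] <- 2L
      next
    }
    conv[v] <- fit$converged
    th <- unclass(fit$theta_hat)
    for (p in params_to_map) maps[[p]][v] <- th[[p]]
    wrss_map[v] <- fit$wrss
  }
  structure(list(maps = maps, wrss = wrss_map, failure = fail,
                 converged = conv, mask = mask,
                 voxel_mm = img$voxel_mm, affine = img$affine,
                 model = model),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("<parametric_maps %s> %s; %d masked voxels, %d failed\n",
              x$model, paste(names(x$maps), collapse = ", "),
              sum(x$mask), sum(x$failure > 0, na.rm = TRUE)))
  invisible(x)
}

#' Write parametric maps as NIfTI files
#'
#' One 3-D NIfTI per parameter (`<prefix>_<param>.nii.gz`, float32,
#' carrying the source voxel size) plus `<prefix>_maps.json` recording the
#' parameters, model and failure counts.
#'
#' @param maps A `parametric_maps` object from [fit_voxelwise()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_maps <- function(maps, dir, prefix = "map") {
  stopifnot(inherits(maps, "parametric_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (p in names(maps$maps)) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, p))
    arr <- maps$maps[[p]]
    attr(arr, "pixdim") <- maps$voxel_mm
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), f)
    files <- c(files, f)
  }
  meta <- file.path(dir, sprintf("%s_maps.json", prefix))
  jsonlite::write_json(
    list(model = maps$model, parameters = names(maps$maps),
         n_masked = sum(maps$mask),
         n_failed = sum(maps$failure > 0, na.rm = TRUE)),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta))
}
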