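# Synthetic-data generation emulating the short liver protocol: parametric
# dual inputs, noisy ROI TAC cohorts with HCC / background-liver parameter
# distributions, and 4-D lesion phantoms.  All generators are pure functions
# of (spec, seed).

#' Reference kinetic parameter distributions
#'
#' Group means and SDs (HCC lesions vs background liver) used as defaults by
#' the cohort and phantom generators.  They reproduce the clinically
#' reported magnitudes for dual-input liver FDG kinetics: HCC shows higher
#' K1, k2, k3 and a predominantly arterial supply (high HPI), while its ER
#' sequestration rate k5 runs lower than background liver.
#'
#' @param model `"4C"` or `"3C"`.
#' @param group `"HCC"` or `"liver"`.
#' @return A list with `mean` (a `kinetic_params` object) and `sd` (named
#'   numeric vector).
#' @export
default_group_params <- function(model = c("4C", "3C"),
                                 group = c("HCC", "liver")) {
  model <- match.arg(model)
  group <- match.arg(group)
  if (model == "4C") {
    if (group == "HCC")
      list(mean = kinetic_params_4c(K1 = 1.441, k2 = 1.018, k3 = 1.348,
                                    k5 = 0.978, k6 = 0.037, HPI = 0.836,
                                    Vb = 0.075, Vi = 0.540, v = 0.317),
           sd = c(K1 = 0.314, k2 = 0.448, k3 = 0.216, k5 = 0.490,
                  k6 = 0.050, HPI = 0.237, Vb = 0.133, Vi = 0.399,
                  v = 0.438))
    else
      list(mean = kinetic_params_4c(K1 = 1.179, k2 = 0.704, k3 = 1.103,
                                    k5 = 1.372, k6 = 0.038, HPI = 0.254,
                                    Vb = 0.029, Vi = 0.286, v = 0.063),
           sd = c(K1 = 0.465, k2 = 0.491, k3 = 0.509, k5 = 0.506,
                  k6 = 0.053, HPI = 0.286, Vb = 0.058, Vi = 0.430,
                  v = 0.215))
  } else {
    if (group == "HCC")
      list(mean = kinetic_params_3c(K1 = 1.302, k2 = 1.435, k3 = 0.047,
                                    k4 = 0.026, HPI = 0.652, Vb = 0.208),
           sd = c(K1 = 0.294, k2 = 0.298, k3 = 0.055, k4 = 0.040,
                  HPI = 0.328, Vb = 0.176))
    else
      list(mean = kinetic_params_3c(K1 = 1.235, k2 = 1.260, k3 = 0.017,
                                    k4 = 0.041, HPI = 0.207, Vb = 0.043),
           sd = c(K1 = 0.418, k2 = 0.406, k3 = 0.030, k4 = 0.053,
                  HPI = 0.207, Vb = 0.062))
  }
}

# One truncated-normal draw on [lo, hi] via the inverse CDF.
rtruncnorm1 <- function(m, s, lo, hi) {
  if (m < lo - 6 * max(s, 1e-12) || m > hi + 6 * max(s, 1e-12))
    stop("infeasible truncation: mean lies far outside the bounds")
  if (s <= 0) return(min(max(m, lo), hi))
  plo <- stats::pnorm(lo, m, s)
  phi <- stats::pnorm(hi, m, s)
  m + s * stats::qnorm(stats::runif(1, plo, phi), 0, 1)
}

# Natural-space truncation bounds matching the fitting box.
draw_bounds <- function(model) {
  if (model == "4C")
    list(lo = c(K1 = 0, k2 = 0, k3 = 0, k5 = 0, k6 = 0, HPI = 0, Vb = 0,
                Vi = 0, v = 0),
         hi = c(K1 = 5, k2 = 5, k3 = 5, k5 = 5, k6 = 1, HPI = 1, Vb = 1,
                Vi = 1, v = 5))
  else
    list(lo = c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, HPI = 0, Vb = 0),
         hi = c(K1 = 5, k2 = 5, k3 = 5, k4 = 1, HPI = 1, Vb = 1))
}

#' Draw kinetic parameter sets for one group
#'
#' Independent truncated-normal draws per parameter (truncation at the
#' fitting bounds; the interstitial fraction Vi is additionally truncated to
#' `[0, 1 - Vb]` after Vb is drawn).  Uses the current RNG state.
#'
#' @param n Number of draws.
#' @param dist A list with `mean`/`sd` as returned by
#'   [default_group_params()].
#' @return List of `kinetic_params` objects.
#' @export
draw_group_params <- function(n, dist) {
  model <- if (inherits(dist$mean, "kinetic_params_4c")) "4C" else "3C"
  b <- draw_bounds(model)
  m <- unlist(dist$mean)
  s <- dist$sd[names(m)]
  lapply(seq_len(n), function(i) {
    x <- m
    for (nm in names(m)) {
      hi <- if (nm == "Vi") 1 - x[["Vb"]] else b$hi[[nm]]
      x[[nm]] <- rtruncnorm1(m[[nm]], s[[nm]], b$lo[[nm]], hi)
    }
    if (model == "4C") do.call(kinetic_params_4c, as.list(x))
    else do.call(kinetic_params_3c, as.list(x))
  })
}

#' Generate a synthetic dual-input pair
#'
#' A parametric arterial bolus (peak about 30 s post-injection) and its
#' dispersed, delayed portal counterpart, sampled on a 0.1-s grid covering
#' the full protocol (0-3660 s).  A small seeded jitter on the bolus
#' amplitude, arrival time and dispersion constant makes different seeds
#' produce different but equally realistic input pairs.
#'
#' @param seed Integer seed.
#' @param t_max End of the sampled grid (s).
#' @return A list with `arterial` and `portal` [sampled_curve()]s.
#' @export
gen_inputs <- function(seed = 1L, t_max = 3660) {
  with_seed(seed, {
    amp <- stats::runif(1, 0.9, 1.1)
    ap <- arterial_model_params(t_delay = stats::runif(1, 12, 18),
                                A1 = 800 * amp, A2 = 15 * amp, A3 = 8 * amp)
    pp <- portal_model_params(tau = stats::runif(1, 20, 30),
                              extra_delay = stats::runif(1, 3, 7))
    grid <- seq(0, t_max, by = 0.1)
    a <- sampled_curve(grid, eval_feng_arterial(ap, grid))
    list(arterial = a, portal = portal_from_arterial(a, pp, grid))
  })
}

#' Cohort generation specification
#'
#' @param n_hcc,n_liver ROI counts per group (defaults: 28 HCC lesions,
#'   24 background-liver ROIs, a typical clinical liver cohort).
#' @param model `"4C"` or `"3C"`.
#' @param hcc,liver Group parameter distributions
#'   (see [default_group_params()]).
#' @param noise Noise level: relative SD at the last dynamic frame of the
#'   liver-group mean TAC (0 disables noise).
#' @param seed Integer seed.
#' @param schedule Acquisition [frame_schedule()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hcc = 28, n_liver = 24, model = c("4C", "3C"),
                        hcc = default_group_params(model, "HCC"),
                        liver = default_group_params(model, "liver"),
                        noise = 0.05, seed = 1L,
                        schedule = default_schedule(FALSE)) {
  model <- match.arg(model)
  if (n_hcc < 1 || n_liver < 1) stop("group sizes must be at least 1")
  if (noise < 0) stop("noise level must be nonnegative")
  structure(list(n_hcc = n_hcc, n_liver = n_liver, model = model,
                 hcc = hcc, liver = liver, noise = noise,
                 seed = as.integer(seed), schedule = schedule),
            class = "cohort_spec")
}

# Frame-noise scale: sigma_i^2 = s * C_i / dt_i with s calibrated so that
# `noise` is the relative SD at the last dynamic frame of the liver-group
# mean TAC.
noise_scale <- function(noise, ref_tac) {
  keep <- dynamic_frame_mask(ref_tac$schedule)
  i <- max(which(keep))
  c_ref <- ref_tac$c[i]
  dt_ref <- frame_durations(ref_tac$schedule)[i]
  noise^2 * c_ref * dt_ref
}

add_frame_noise <- function(x, s) {
  if (s == 0) return(x)
  dt <- frame_durations(x$schedule)
  sd_i <- sqrt(s * pmax(x$c, 0) / dt)
  tac(x$schedule, pmax(x$c + stats::rnorm(length(x$c), 0, sd_i), 0), x$w)
}

#' Generate a synthetic ROI cohort
#'
#' Draws ground-truth parameter sets per ROI from the group distributions,
#' forward-simulates each TAC on the spec's schedule with a shared
#' seed-derived dual-input pair, and adds frame-duration-dependent Gaussian
#' noise (variance proportional to signal / frame duration, the usual PET
#' count-statistics surrogate), clipped at zero.  Fully deterministic per
#' spec + seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `truth` (data frame of group, subject id and generating
#'   parameters), `tacs` (list of noisy [tac()]s, same order), `arterial`,
#'   `portal`, and `noise_scale`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  inputs <- gen_inputs(spec$seed,
                       t_max = spec$schedule$frame_end[n_frames(spec$schedule)] + 30)
  liver_mean_tac <- simulate_tac(spec$liver$mean, inputs$arterial,
                                 inputs$portal, spec$schedule)
  s <- noise_scale(spec$noise, liver_mean_tac)
  with_seed(spec$seed + 1L, {
    th_hcc <- draw_group_params(spec$n_hcc, spec$hcc)
    th_liv <- draw_group_params(spec$n_liver, spec$liver)
    theta <- c(th_hcc, th_liv)
    group <- c(rep("HCC", spec$n_hcc), rep("liver", spec$n_liver))
    subject <- c(seq_len(spec$n_hcc), seq_len(spec$n_liver))
    tacs <- lapply(theta, function(p) {
      add_frame_noise(simulate_tac(p, inputs$arterial, inputs$portal,
                                   spec$schedule), s)
    })
    truth <- cbind(data.frame(group = group, subject = subject,
                              model = spec$model),
                   do.call(rbind, lapply(theta, function(p)
                     as.data.frame(unclass(p)))))
    list(truth = truth, tacs = tacs, arterial = inputs$arterial,
         portal = inputs$portal, noise_scale = s)
  })
}

#' Phantom generation specification
#'
#' A digital liver slab on a small 3-D grid: a background of liver-like
#' kinetics containing one spherical HCC-like lesion, scanned with the
#' 17-frame protocol.  The liver occupies an in-plane ellipse on every
#' slice; voxels outside it are empty (air).
#'
#' @param dim Grid dimensions `c(nx, ny, nz)`.
#' @param voxel_mm Voxel size in mm.
#' @param lesion_centre Lesion centre (voxel coordinates, 1-based).
#' @param lesion_radius Lesion radius in voxels.
#' @param lesion,background `kinetic_params` for the two tissues.
#' @param liver_semiaxes In-plane semi-axes (voxels) of the liver ellipse.
#' @param noise Noise level as in [cohort_spec()].
#' @param seed Integer seed.
#' @param schedule Acquisition schedule (default: 17 frames including the
#'   60-min static frame, as used for parametric imaging).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(32, 32, 4), voxel_mm = c(4, 4, 4),
                         lesion_centre = c(20, 15, 2), lesion_radius = 3.5,
                         lesion = default_group_params("4C", "HCC")$mean,
                         background = default_group_params("4C", "liver")$mean,
                         liver_semiaxes = c(13, 11),
                         noise = 0.05, seed = 1L,
                         schedule = default_schedule(TRUE)) {
  if (length(dim) != 3L || any(dim < 1)) stop("`dim` must be 3 positive sizes")
  if (any(lesion_centre < 1) || any(lesion_centre > dim))
    stop("lesion centre outside the grid")
  if (lesion_centre[1] + lesion_radius > dim[1] ||
      lesion_centre[1] - lesion_radius < 1 ||
      lesion_centre[2] + lesion_radius > dim[2] ||
      lesion_centre[2] - lesion_radius < 1)
    stop("lesion extends outside the grid")
  structure(list(dim = dim, voxel_mm = voxel_mm,
                 lesion_centre = lesion_centre,
                 lesion_radius = lesion_radius, lesion = lesion,
                 background = background, liver_semiaxes = liver_semiaxes,
                 noise = noise, seed = as.integer(seed), schedule = schedule),
            class = "phantom_spec")
}

#' Generate a 4-D lesion phantom
#'
#' Every liver voxel's TAC is the forward-simulated lesion or background
#' curve plus independent frame-duration-dependent noise; voxels outside the
#' liver ellipse are zero.  Ground-truth label and mask volumes are returned
#' for map validation.  Deterministic per spec + seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `image` ([dynamic_image()]), `mask` (liver voxels),
#'   `label` (1 = lesion, 0 = background liver, NA outside), `lesion_tac`,
#'   `background_tac` (noiseless), `arterial`, `portal`.
#' @export
gen_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sched <- spec$schedule
  inputs <- gen_inputs(spec$seed,
                       t_max = sched$frame_end[n_frames(sched)] + 30)
  tac_les <- simulate_tac(spec$lesion, inputs$arterial, inputs$portal, sched)
  tac_bg <- simulate_tac(spec$background, inputs$arterial, inputs$portal,
                         sched)
  s <- noise_scale(spec$noise, tac_bg)
  d <- spec$dim
  cx <- (d[1] + 1) / 2
  cy <- (d[2] + 1) / 2
  xi <- slice.index(array(0, d), 1)
  yi <- slice.index(array(0, d), 2)
  zi <- slice.index(array(0, d), 3)
  mask <- ((xi - cx) / spec$liver_semiaxes[1])^2 +
    ((yi - cy) / spec$liver_semiaxes[2])^2 <= 1
  lesion <- (xi - spec$lesion_centre[1])^2 + (yi - spec$lesion_centre[2])^2 +
    (zi - spec$lesion_centre[3])^2 <= spec$lesion_radius^2
  if (!all(lesion <= mask))
    stop("lesion must lie inside the liver region")
  label <- array(NA_real_, d)
  label[mask] <- 0
  label[lesion] <- 1
  nf <- n_frames(sched)
  dt <- frame_durations(sched)
  data <- array(0, c(d, nf))
  vox <- which(mask)
  with_seed(spec$seed + 2L, {
    for (v in vox) {
      base <- if (lesion[v]) tac_les$c else tac_bg$c
      sd_i <- sqrt(s * pmax(base, 0) / dt)
      idx <- arrayInd(v, d)
      data[idx[1], idx[2], idx[3], ] <-
        pmax(base + stats::rnorm(nf, 0, sd_i), 0)
    }
  })
  list(image = dynamic_image(data, sched, voxel_mm = spec$voxel_mm),
       mask = mask, label = label, lesion_tac = tac_les,
       background_tac = tac_bg, arterial = inputs$arterial,
       portal = inputs$portal)
}
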