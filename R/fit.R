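# Weighted nonlinear least-squares estimation of the kinetic parameters by
# multistart Levenberg-Marquardt (minpack.lm), and least-squares AIC model
# comparison.  The interstitial fraction is fitted through the
# reparameterisation Vi = (1 - Vb) * u, u in [0, 1], which enforces
# Vb + Vi <= 1 inside box bounds.

free_param_names <- function(model) {
  if (model == "4C") c("K1", "k2", "k3", "k5", "k6", "HPI", "Vb", "u", "v")
  else c("K1", "k2", "k3", "k4", "HPI", "Vb")
}

default_bounds <- function(model) {
  if (model == "4C")
    list(lower = c(K1 = 0, k2 = 0, k3 = 0, k5 = 0, k6 = 0, HPI = 0,
                   Vb = 0, u = 0, v = 0),
         upper = c(K1 = 5, k2 = 5, k3 = 5, k5 = 5, k6 = 1, HPI = 1,
                   Vb = 1, u = 1, v = 5))
  else
    list(lower = c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, HPI = 0, Vb = 0),
         upper = c(K1 = 5, k2 = 5, k3 = 5, k4 = 1, HPI = 1, Vb = 1))
}

#' Fitting configuration
#'
#' Controls for [fit_tac()] and [fit_voxelwise()].
#'
#' @param n_starts Number of Latin-hypercube multistart points (>= 1).  The
#'   best (lowest-WRSS) run wins; ties break to the lowest start index.
#' @param seed Integer seed making the start draw, and hence the whole fit,
#'   deterministic.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param tol Convergence tolerance (`ftol`/`ptol` of the LM run).
#' @param bounds Optional named list overriding entries of the default box
#'   bounds, e.g. `list(upper = c(v = 10))`.  Defaults cover the reported
#'   clinical parameter ranges with headroom: K1, k2, k3, k5 in [0, 5]
#'   min^-1; k4, k6 in [0, 1] min^-1; HPI, Vb (and the Vi fraction u) in
#'   [0, 1]; v in [0, 5].
#' @param fixed Named list of parameters frozen at given values (removed
#'   from the optimisation), e.g. `list(k6 = 0.04)` for voxelwise fits.
#' @param weight_scheme Weight scheme used when a TAC carries no weights of
#'   its own (see [simulate_tac()]).
#' @param include_static_frame Should a late static frame (separated from
#'   the contiguous dynamic block by an acquisition gap) enter ROI fits?
#'   Default `FALSE`, matching the 16-frame dynamic analysis; parametric
#'   imaging always uses all frames.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_starts = 20, seed = 1L, max_iter = 300,
                       tol = 1e-12, bounds = NULL, fixed = list(),
                       weight_scheme = "frame_duration",
                       include_static_frame = FALSE) {
  if (n_starts < 1) stop("`n_starts` must be at least 1")
  if (tol <= 0) stop("`tol` must be positive")
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 max_iter = as.integer(max_iter), tol = tol,
                 bounds = bounds, fixed = fixed,
                 weight_scheme = weight_scheme,
                 include_static_frame = include_static_frame),
            class = "fit_config")
}

config_bounds <- function(model, cfg) {
  b <- default_bounds(model)
  if (!is.null(cfg$bounds)) {
    for (side in c("lower", "upper")) {
      ov <- cfg$bounds[[side]]
      if (!is.null(ov)) b[[side]][names(ov)] <- ov
    }
  }
  if (any(b$lower > b$upper)) stop("lower bounds exceed upper bounds")
  b
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

params_from_free <- function(model, x) {
  if (model == "4C")
    kinetic_params_4c(K1 = x[["K1"]], k2 = x[["k2"]], k3 = x[["k3"]],
                      k5 = x[["k5"]], k6 = x[["k6"]], HPI = x[["HPI"]],
                      Vb = x[["Vb"]], Vi = (1 - x[["Vb"]]) * x[["u"]],
                      v = x[["v"]])
  else
    kinetic_params_3c(K1 = x[["K1"]], k2 = x[["k2"]], k3 = x[["k3"]],
                      k4 = x[["k4"]], HPI = x[["HPI"]], Vb = x[["Vb"]])
}

free_from_params <- function(model, p) {
  if (model == "4C")
    c(K1 = p$K1, k2 = p$k2, k3 = p$k3, k5 = p$k5, k6 = p$k6, HPI = p$HPI,
      Vb = p$Vb, u = if (p$Vb < 1) p$Vi / (1 - p$Vb) else 0, v = p$v)
  else
    c(K1 = p$K1, k2 = p$k2, k3 = p$k3, k4 = p$k4, HPI = p$HPI, Vb = p$Vb)
}

# Frames belonging to the contiguous dynamic block: a gap of more than 60 s
# between consecutive frames marks the start of a separate static acquisition.
dynamic_frame_mask <- function(sched) {
  nf <- n_frames(sched)
  if (nf == 1L) return(TRUE)
  gaps <- sched$frame_start[-1L] - sched$frame_end[-nf]
  first_gap <- which(gaps > 60)[1]
  if (is.na(first_gap)) rep(TRUE, nf)
  else seq_len(nf) <= first_gap
}

# Precompute everything shared between fits on the same schedule/inputs.
make_fit_context <- function(sched, a, pv, model, cfg) {
  grid <- sim_grid(sched$frame_end[n_frames(sched)])
  idx <- frame_indices(grid, sched)
  list(model = model, sched = sched, grid = grid,
       a_grid = eval_curve(a, grid), p_grid = eval_curve(pv, grid),
       start0 = idx$start - 1L, end0 = idx$end - 1L,
       cfg = cfg, bounds = config_bounds(model, cfg))
}

ctx_sim <- function(ctx, x) {
  if (ctx$model == "4C") {
    M <- matrix(c(-(x[["k2"]] + x[["k3"]]), x[["k3"]], 0,
                  0, -x[["k5"]], x[["k5"]],
                  x[["k6"]], 0, -x[["k6"]]), nrow = 3)
    vr <- x[["v"]] / (1 + x[["v"]])
    Vi <- (1 - x[["Vb"]]) * x[["u"]]
    rest <- 1 - x[["Vb"]] - Vi
    alpha <- c(Vi + (1 - vr) * rest, (1 - vr) * rest, vr * rest)
  } else {
    M <- matrix(c(-(x[["k2"]] + x[["k3"]]), x[["k3"]],
                  x[["k4"]], -x[["k4"]]), nrow = 2)
    alpha <- c(1 - x[["Vb"]], 1 - x[["Vb"]])
  }
  cb <- x[["HPI"]] * ctx$a_grid + (1 - x[["HPI"]]) * ctx$p_grid
  as.numeric(.cpp_sim_frames(M, x[["K1"]], alpha, x[["Vb"]], ctx$grid, cb,
                             ctx$start0, ctx$end0))
}

fit_tac_ctx <- function(ctx, cvals, wvals, extra_starts = list()) {
  cfg <- ctx$cfg
  if (all(cvals == 0)) stop("degenerate data: TAC is identically zero")
  all_names <- free_param_names(ctx$model)
  fixed <- unlist(cfg$fixed)
  if (!is.null(fixed) && "Vi" %in% names(fixed))
    stop("freeze `u` (the Vi fraction of 1 - Vb) rather than Vi")
  free <- setdiff(all_names, names(fixed))
  lo <- ctx$bounds$lower[free]
  hi <- ctx$bounds$upper[free]
  sw <- sqrt(wvals)

  resid_fn <- function(par) {
    x <- c(par, fixed)[all_names]
    names(x) <- all_names
    sw * (ctx_sim(ctx, x) - cvals)
  }

  np <- length(free)
  starts <- with_seed(cfg$seed, lhs::randomLHS(cfg$n_starts, np))
  starts <- sweep(sweep(starts, 2, hi - lo, "*"), 2, lo, "+")
  colnames(starts) <- free
  start_list <- lapply(seq_len(nrow(starts)), function(i) starts[i, ])
  for (es in extra_starts)
    start_list[[length(start_list) + 1L]] <- pmin(pmax(es[free], lo), hi)

  ctrl <- minpack.lm::nls.lm.control(maxiter = cfg$max_iter,
                                     maxfev = 20L * cfg$max_iter * (np + 1L),
                                     ftol = cfg$tol, ptol = cfg$tol)
  best <- NULL
  best_w <- Inf
  best_i <- NA_integer_
  trace <- numeric(length(start_list))
  for (i in seq_along(start_list)) {
    f <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = start_list[[i]], lower = lo, upper = hi,
                           fn = resid_fn, control = ctrl)),
      error = function(e) NULL)
    trace[i] <- if (is.null(f)) Inf else f$deviance
    if (!is.null(f) && f$deviance < best_w) {
      best <- f
      best_w <- f$deviance
      best_i <- i
    }
  }
  if (is.null(best))
    return(structure(list(theta_hat = NULL, wrss = Inf, aic = Inf,
                          n_frames = length(cvals), n_params = np,
                          converged = FALSE, start_index = NA_integer_,
                          wrss_trace = trace, model = ctx$model),
                     class = "kinetic_fit"))
  x <- c(unlist(best$par), fixed)[all_names]
  names(x) <- all_names
  theta <- params_from_free(ctx$model, x)
  structure(list(theta_hat = theta, wrss = best_w,
                 aic = aic_ls(best_w, length(cvals), np),
                 n_frames = length(cvals), n_params = np,
                 converged = best$info %in% 1:4, start_index = best_i,
                 wrss_trace = trace, model = ctx$model),
            class = "kinetic_fit")
}

#' Fit a kinetic model to a time-activity curve
#'
#' Weighted nonlinear least squares: minimises
#' `WRSS(theta) = sum_i w_i (c_i - C_T(t_i; theta))^2` over the frames with
#' bounded Levenberg-Marquardt from `n_starts` Latin-hypercube starting
#' points (plus any `extra_starts`); the lowest-WRSS run is returned.
#' Deterministic for a given configuration.
#'
#' @param x A [tac()] (its weights are used as the `w_i`).
#' @param a,pv Arterial and portal input [sampled_curve()]s.
#' @param model `"3C"` or `"4C"`.
#' @param cfg A [fit_config()].
#' @param extra_starts Optional list of `kinetic_params` objects added as
#'   additional starting points.
#' @return A `kinetic_fit`: `theta_hat`, `wrss`, `aic`, `n_frames`,
#'   `n_params` (number of free parameters), `converged`, `start_index`,
#'   `wrss_trace`.
#' @export
fit_tac <- function(x, a, pv, model = c("4C", "3C"), cfg = fit_config(),
                    extra_starts = list()) {
  stopifnot(inherits(x, "tac"))
  model <- match.arg(model)
  sched <- x$schedule
  cvals <- x$c
  wvals <- x$w
  if (!cfg$include_static_frame) {
    keep <- dynamic_frame_mask(sched)
    if (!all(keep)) {
      sched <- frame_schedule(sched$frame_start[keep], sched$frame_end[keep])
      cvals <- cvals[keep]
      wvals <- wvals[keep]
    }
  }
  np <- length(setdiff(free_param_names(model), names(unlist(cfg$fixed))))
  if (length(cvals) < np + 1L)
    stop("TAC has too few frames for the number of free parameters")
  ctx <- make_fit_context(sched, a, pv, model, cfg)
  es <- lapply(extra_starts, function(p) free_from_params(model, p))
  fit_tac_ctx(ctx, cvals, wvals, extra_starts = es)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit %s> WRSS %.4g, AIC %.4g, converged %s (start %s)\n",
              x$model, x$wrss, x$aic, x$converged, x$start_index))
  if (!is.null(x$theta_hat)) print(x$theta_hat)
  invisible(x)
}

#' Weighted residual sum of squares
#'
#' `WRSS(theta) = sum_i w_i (c_i - C_T(t_i; theta))^2` over the TAC frames,
#' the objective minimised by [fit_tac()].
#'
#' @param theta A `kinetic_params` object.
#' @param x A [tac()].
#' @param a,pv Input [sampled_curve()]s.
#' @return Nonnegative scalar.
#' @export
wrss <- function(theta, x, a, pv) {
  stopifnot(inherits(theta, "kinetic_params"), inherits(x, "tac"))
  chat <- simulate_tac(theta, a, pv, x$schedule)$c
  sum(x$w * (x$c - chat)^2)
}

#' Least-squares AIC
#'
#' `AIC = N log(WRSS / N) + 2 P`, the Akaike information criterion for a
#' least-squares fit with `N` frames and `P` estimated parameters (9 for the
#' full 4C model, 6 for the 3C model).  Lower is better; the constant terms
#' common to both models are dropped.
#'
#' @param wrss Weighted residual sum of squares, > 0.
#' @param n_frames Number of fitted frames N.
#' @param n_params Number of estimated parameters P.
#' @return The AIC score; `-Inf` (with a warning) when `wrss <= 0`.
#' @export
aic_ls <- function(wrss, n_frames, n_params) {
  if (n_frames <= n_params)
    stop("AIC requires more frames than parameters")
  if (!is.finite(wrss) || wrss <= 0) {
    warning("WRSS is zero or non-finite; AIC is -Inf")
    return(-Inf)
  }
  n_frames * log(wrss / n_frames) + 2 * n_params
}

# Embed a fitted 3C parameter set as a 4C starting point.  k4 = 0 reduces
# exactly (k5 = k6 = 0, Vi = 0, v = 0); for k4 > 0 the return path is
# approximated by M -> R at k5 = k4 with fast ER clearance.
seed_4c_from_3c <- function(p3, k6_upper = 1) {
  if (p3$k4 < 1e-8)
    kinetic_params_4c(K1 = p3$K1, k2 = p3$k2, k3 = p3$k3, k5 = 0, k6 = 0,
                      HPI = p3$HPI, Vb = p3$Vb, Vi = 0, v = 0)
  else
    kinetic_params_4c(K1 = p3$K1, k2 = p3$k2, k3 = p3$k3, k5 = p3$k4,
                      k6 = k6_upper, HPI = p3$HPI, Vb = p3$Vb, Vi = 0, v = 0)
}

#' Fit a kinetic model to every TAC of a cohort
#'
#' Convenience wrapper running [fit_tac()] over a list of TACs with shared
#' inputs and assembling the estimates into a cohort table.  With
#' `reweight = TRUE` each fit is refined by one model-based
#' inverse-variance reweighting round: after an initial frame-duration-
#' weighted fit, weights are reset to `dt_i / max(Chat_i, 0.05 max(Chat))`
#' (the inverse of the frame-count noise variance, with the model
#' prediction in place of the noisy measurement) and the fit is repeated
#' from the first optimum plus fresh starts.  This matches the variance
#' structure of frame-binned PET data and stabilises the perfusion
#' parameters estimated from the short early frames.
#'
#' @param tacs List of [tac()] objects.
#' @param a,pv Shared input [sampled_curve()]s.
#' @param model `"4C"` or `"3C"`.
#' @param cfg A [fit_config()].
#' @param reweight Apply the model-based reweighting round?
#' @return A data frame: one row per TAC with the fitted parameters,
#'   `wrss`, `aic` and `converged`.
#' @export
fit_cohort <- function(tacs, a, pv, model = c("4C", "3C"),
                       cfg = fit_config(), reweight = FALSE) {
  model <- match.arg(model)
  rows <- lapply(seq_along(tacs), function(i) {
    x <- tacs[[i]]
    f <- fit_tac(x, a, pv, model = model, cfg = cfg)
    if (reweight && !is.null(f$theta_hat)) {
      chat <- simulate_tac(f$theta_hat, a, pv, x$schedule)$c
      dt <- frame_durations(x$schedule)
      w <- dt / pmax(chat, 0.05 * max(chat))
      f <- fit_tac(tac(x$schedule, x$c, w), a, pv, model = model, cfg = cfg,
                   extra_starts = list(f$theta_hat))
    }
    cbind(data.frame(roi = i), as.data.frame(unclass(f$theta_hat)),
          data.frame(wrss = f$wrss, aic = f$aic, converged = f$converged))
  })
  do.call(rbind, rows)
}

#' Fit and compare the 3C and 4C models on one TAC
#'
#' Fits both models on the same data and reports
#' `delta_aic = AIC_4C - AIC_3C`; the model with the lower AIC is preferred.
#' The 3C optimum seeds one additional 4C start (the 3C model is nested in
#' the 4C model), so `WRSS_4C <= WRSS_3C` up to optimiser tolerance.
#'
#' @inheritParams fit_tac
#' @return A list: `fit_3c`, `fit_4c`, `delta_aic`, `preferred`.
#' @export
compare_models <- function(x, a, pv, cfg = fit_config()) {
  fit3 <- fit_tac(x, a, pv, model = "3C", cfg = cfg)
  extra <- if (!is.null(fit3$theta_hat)) {
    k6u <- config_bounds("4C", cfg)$upper[["k6"]]
    list(seed_4c_from_3c(fit3$theta_hat, k6_upper = k6u))
  } else list()
  fit4 <- fit_tac(x, a, pv, model = "4C", cfg = cfg, extra_starts = extra)
  delta <- fit4$aic - fit3$aic
  list(fit_3c = fit3, fit_4c = fit4, delta_aic = delta,
       preferred = if (delta < 0) "4C" else "3C")
}
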