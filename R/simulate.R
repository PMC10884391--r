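# Forward simulation: exact matrix-exponential propagation on a fine grid
# (0.1 s during the first 300 s, 1 s beyond), with the blood input treated
# as piecewise linear within each step.  Time in seconds, rates in min^-1;
# the unit conversion happens once, inside the compiled solver.

# Fine simulation grid covering [0, t_max].  Frame boundaries of the
# standard schedules (multiples of 5 s up to 300 s; integer seconds after)
# fall exactly on grid nodes.
sim_grid <- function(t_max) {
  if (!is.finite(t_max) || t_max <= 0) stop("t_max must be positive")
  g <- (0:(round(min(t_max, 300) * 10))) / 10
  if (t_max > 300) g <- c(g, seq(301, ceiling(t_max), by = 1))
  g
}

# Indices (1-based) of the frame boundaries within a grid.
frame_indices <- function(grid, sched) {
  key <- round(grid, 6)
  s <- match(round(sched$frame_start, 6), key)
  e <- match(round(sched$frame_end, 6), key)
  if (any(is.na(s)) || any(is.na(e)))
    stop("frame boundaries do not lie on the simulation grid")
  list(start = s, end = e)
}

#' Solve the compartmental state equations
#'
#' Integrates `dC/dt = M C + K1 C_B(t) e1` with `C(0) = 0`, where the
#' forcing enters only the first (free-FDG) state.  Propagation uses the
#' exact matrix exponential per grid step with piecewise-linear input, so
#' the solution is exact for a piecewise-linear `C_B` up to round-off.
#'
#' @param M Rate matrix (min^-1), e.g. from [system_matrix()].
#' @param K1 Transport rate constant (min^-1).
#' @param cb The blood input: a function of time (s) or a [sampled_curve()].
#' @param grid Strictly increasing times (s) starting at 0.
#' @return A `state_trajectory`: list with `times` and `states`
#'   (matrix, one row per compartment).
#' @export
solve_states <- function(M, K1, cb, grid) {
  grid <- as.numeric(grid)
  if (grid[1] != 0) stop("`grid` must start at 0")
  cbv <- if (inherits(cb, "sampled_curve")) eval_curve(cb, grid) else cb(grid)
  if (any(!is.finite(cbv))) stop("blood input evaluates to non-finite values")
  st <- .cpp_solve_states(M, K1, grid, cbv)
  rownames(st) <- rownames(M)
  structure(list(times = grid, states = st, cb = cbv),
            class = "state_trajectory")
}

#' Measured tissue concentration from a state trajectory
#'
#' `C_T(t) = alpha . C(t) + Vb C_B(t)`: the compartment concentrations mixed
#' by their volume weights plus the blood spill-in.
#'
#' @param traj A `state_trajectory` from [solve_states()].
#' @param alpha Numeric weight vector (from [alpha_weights()]`$alpha`),
#'   length equal to the number of compartments.
#' @param Vb Fractional blood volume.
#' @param cb The blood input (function or [sampled_curve()]); defaults to
#'   the input stored with the trajectory.
#' @return A list with `times` and `values` (the continuous output curve on
#'   the trajectory grid).
#' @export
tissue_output <- function(traj, alpha, Vb, cb = NULL) {
  stopifnot(inherits(traj, "state_trajectory"))
  if (length(alpha) != nrow(traj$states))
    stop("`alpha` length must match the number of compartments")
  cbv <- if (is.null(cb)) traj$cb
  else if (inherits(cb, "sampled_curve")) eval_curve(cb, traj$times)
  else cb(traj$times)
  list(times = traj$times,
       values = as.numeric(crossprod(traj$states, as.numeric(alpha))) +
         Vb * cbv)
}

#' Frame-average a continuous curve
#'
#' The PET measurement of frame i is the time average of the tissue curve
#' over the frame: `(1/dt_i) * integral of C_T over [start_i, end_i]`,
#' computed by trapezoidal quadrature on the curve's grid (frame boundaries
#' are interpolated onto the grid if they fall between nodes).
#'
#' @param ct A list with `times` and `values` (e.g. from [tissue_output()]).
#' @param sched A [frame_schedule()].
#' @return Numeric vector of frame means.
#' @export
frame_average <- function(ct, sched) {
  stopifnot(inherits(sched, "frame_schedule"))
  tt <- ct$times
  vv <- ct$values
  if (sched$frame_start[1] < tt[1] ||
      sched$frame_end[n_frames(sched)] > tt[length(tt)] + 1e-9)
    stop("frame schedule extends beyond the curve's support")
  b <- sort(unique(c(tt, sched$frame_start, sched$frame_end)))
  vb <- stats::approx(tt, vv, xout = b)$y
  cum <- c(0, cumsum(0.5 * (vb[-1] + vb[-length(vb)]) * diff(b)))
  ci <- function(x) cum[match(round(x, 9), round(b, 9))]
  (ci(sched$frame_end) - ci(sched$frame_start)) / frame_durations(sched)
}

#' Simulate a time-activity curve
#'
#' The full forward pipeline for one parameter set: combine the arterial and
#' portal inputs with the parameter's HPI, solve the compartmental states,
#' form the tissue output with blood spill-in, and average over the
#' acquisition frames.  Deterministic.
#'
#' @param p A [kinetic_params_4c()] or [kinetic_params_3c()] object.
#' @param a,pv Arterial and portal [sampled_curve()]s covering the schedule.
#' @param sched A [frame_schedule()].
#' @param weight_scheme Weighting attached to the returned TAC:
#'   `"frame_duration"` (default), `"uniform"`, or `"inverse_variance"`
#'   (`dt_i / max(c_i, eps)`).
#' @return A [tac()].
#' @export
simulate_tac <- function(p, a, pv, sched,
                         weight_scheme = c("frame_duration", "uniform",
                                           "inverse_variance")) {
  stopifnot(inherits(p, "kinetic_params"), inherits(sched, "frame_schedule"))
  weight_scheme <- match.arg(weight_scheme)
  grid <- sim_grid(sched$frame_end[n_frames(sched)])
  idx <- frame_indices(grid, sched)
  cbv <- p$HPI * eval_curve(a, grid) + (1 - p$HPI) * eval_curve(pv, grid)
  aw <- alpha_weights(p)
  cmeans <- as.numeric(.cpp_sim_frames(system_matrix(p), p$K1, aw$alpha,
                                       p$Vb, grid, cbv,
                                       idx$start - 1L, idx$end - 1L))
  tac(sched, cmeans, w = tac_weights(weight_scheme, sched, cmeans))
}

tac_weights <- function(scheme, sched, cmeans, eps = 1e-6) {
  dt <- frame_durations(sched)
  switch(scheme,
         frame_duration = dt,
         uniform = rep(1, n_frames(sched)),
         inverse_variance = dt / pmax(cmeans, eps))
}
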