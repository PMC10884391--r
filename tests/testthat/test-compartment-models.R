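test_that("system matrices follow the compartmental topology", {
  p4 <- kinetic_params_4c(K1 = 1, k2 = 1, k3 = 2, k5 = 3, k6 = 4,
                          HPI = 0.5, Vb = 0.1, Vi = 0.1, v = 0.1)
  M4 <- system_matrix(p4)
  expect_equal(unname(M4),
               matrix(c(-3, 0, 4, 2, -3, 0, 0, 3, -4), 3, byrow = TRUE))
  # tracer leaves the tissue system only through k2
  expect_equal(unname(colSums(M4)), c(-1, 0, 0))

  p3 <- kinetic_params_3c(K1 = 1, k2 = 0.5, k3 = 0.1, k4 = 0.02,
                          HPI = 0.5, Vb = 0.1)
  M3 <- system_matrix(p3)
  expect_equal(unname(M3), matrix(c(-0.6, 0.02, 0.1, -0.02), 2, byrow = TRUE))
  expect_equal(unname(colSums(M3)), c(-0.5, 0))

  # k5 = k6 = 0: upper-left block reduces to the 3C matrix with k4 = 0
  p4r <- kinetic_params_4c(1, 0.5, 0.1, 0, 0, 0.5, 0.1, 0, 0)
  expect_equal(unname(system_matrix(p4r)[1:2, 1:2]),
               matrix(c(-0.6, 0, 0.1, 0), 2, byrow = TRUE))
  p0 <- kinetic_params_4c(0, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(unname(system_matrix(p0)), matrix(0, 3, 3))
  expect_error(kinetic_params_4c(1, -0.1, 1, 1, 0, 0.5, 0.1, 0.1, 0.1),
               "nonnegative")
})

test_that("output mixing weights follow the volume-fraction algebra", {
  a0 <- alpha_weights(kinetic_params_4c(1, 1, 1, 1, 0, 0.5, 0, 0, 0))
  expect_equal(unname(a0$alpha), c(1, 1, 0))
  a1 <- alpha_weights(kinetic_params_4c(1, 1, 1, 1, 0, 0.5,
                                        Vb = 0.2, Vi = 0.3, v = 1))
  expect_equal(a1$v_r, 0.5)
  expect_equal(unname(a1$alpha), c(0.55, 0.25, 0.25))
  a3 <- alpha_weights(kinetic_params_3c(1, 1, 1, 0, 0.5, Vb = 0.208))
  expect_equal(unname(a3$alpha), c(0.792, 0.792))
  expect_error(kinetic_params_4c(1, 1, 1, 1, 0, 0.5, Vb = 0.6, Vi = 0.6,
                                 v = 0), "exceed 1")
})

test_that("the state solver integrates trivial systems exactly", {
  grid <- seq(0, 120, by = 0.1)
  M <- matrix(0, 2, 2)
  # zero forcing: all states stay zero
  st0 <- solve_states(M, 1, function(t) rep(0, length(t)), grid)
  expect_true(all(st0$states == 0))
  # M = 0, constant input: pure integration, C_E = (K1/60) c0 t
  st <- solve_states(M, K1 = 1.2, function(t) rep(2, length(t)), grid)
  expect_equal(st$states[1, ], 1.2 / 60 * 2 * grid, tolerance = 1e-12)
  expect_equal(st$states[2, ], rep(0, length(grid)))
  expect_error(solve_states(M, 1, function(t) rep(NA_real_, length(t)), grid),
               "non-finite")
})

test_that("matrix-exponential propagation matches an adaptive stiff solver", {
  skip_if_not_installed("deSolve")
  inp <- hk_inputs()
  grid <- seq(0, 300, by = 0.1)
  out_t <- seq(0, 300, by = 5)
  set.seed(42)
  for (i in 1:5) {
    p <- kinetic_params_4c(runif(1, 0.5, 2), runif(1, 0.3, 2),
                           runif(1, 0.3, 2), runif(1, 0.1, 2),
                           runif(1, 0, 0.2), runif(1), runif(1, 0, 0.3),
                           runif(1, 0, 0.5), runif(1, 0, 1))
    M <- system_matrix(p)
    cbv <- dual_input(inp$arterial, inp$portal, p$HPI, grid)
    cbf <- stats::approxfun(grid, cbv, yleft = 0, yright = cbv[length(cbv)])
    st <- solve_states(M, p$K1, cbf, grid)
    Ms <- M / 60
    rhs <- function(t, y, parms)
      list(as.numeric(Ms %*% y) + p$K1 / 60 * cbf(t) * c(1, 0, 0))
    o <- deSolve::ode(c(0, 0, 0), out_t, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
    sub <- st$states[, match(out_t, round(grid, 6))]
    expect_lt(max(abs(t(o[, 2:4]) - sub)) / max(abs(o[, 2:4])), 1e-6)
  }
})

test_that("tissue output mixes states and blood spill-in", {
  inp <- hk_inputs()
  grid <- seq(0, 300, by = 0.1)
  p <- hk_p4_hcc
  cbv <- dual_input(inp$arterial, inp$portal, p$HPI, grid)
  cbf <- stats::approxfun(grid, cbv, yleft = 0, yright = cbv[length(cbv)])
  st <- solve_states(system_matrix(p), p$K1, cbf, grid)
  # pure blood voxel
  ct_blood <- tissue_output(st, alpha = c(0, 0, 0), Vb = 1)
  expect_equal(ct_blood$values, cbv, tolerance = 1e-12)
  # no blood: weighted states only
  aw <- alpha_weights(p)
  ct0 <- tissue_output(st, aw$alpha, Vb = 0)
  expect_equal(ct0$values,
               as.numeric(crossprod(st$states, as.numeric(aw$alpha))))
  expect_error(tissue_output(st, c(1, 1), Vb = 0), "match")
})

test_that("frame averaging is exact for constants and ramps", {
  s <- frame_schedule(c(0, 10), c(10, 30))
  cst <- list(times = seq(0, 30, 0.5), values = rep(7, 61))
  expect_equal(frame_average(cst, s), c(7, 7))
  ramp <- list(times = seq(0, 30, 0.5), values = seq(0, 30, 0.5))
  expect_equal(frame_average(ramp, s), c(5, 20))
  expect_error(frame_average(cst, frame_schedule(0, 40)), "support")
})

test_that("frame averaging matches a fine-grid trapezoid oracle on a bolus", {
  p <- arterial_model_params()
  tt <- seq(0, 300, by = 0.1)
  curve <- list(times = tt, values = eval_feng_arterial(p, tt))
  s <- default_schedule(FALSE)
  got <- frame_average(curve, s)
  fine <- seq(0, 300, by = 0.005)
  vf <- eval_feng_arterial(p, fine)
  cum <- c(0, cumsum(0.5 * (vf[-1] + vf[-length(vf)]) * diff(fine)))
  oracle <- (cum[match(s$frame_end, fine)] - cum[match(s$frame_start, fine)]) /
    frame_durations(s)
  expect_equal(got, oracle, tolerance = 1e-5)
})

test_that("the 4C model reduces exactly to the 3C model", {
  set.seed(7)
  for (i in 1:5) {
    inp <- hk_inputs(i)
    K1 <- runif(1, 0.5, 2); k2 <- runif(1, 0.3, 2); k3 <- runif(1, 0.1, 2)
    hpi <- runif(1); vb <- runif(1, 0, 0.3)
    p4 <- kinetic_params_4c(K1, k2, k3, 0, 0, hpi, vb, 0, 0)
    p3 <- kinetic_params_3c(K1, k2, k3, 0, hpi, vb)
    a4 <- simulate_tac(p4, inp$arterial, inp$portal, hk_sched17)
    a3 <- simulate_tac(p3, inp$arterial, inp$portal, hk_sched17)
    expect_lt(max(abs(a4$c - a3$c)), 1e-9)
  }
})

test_that("simulated TACs are linear in K1 and vanish without uptake", {
  inp <- hk_inputs()
  p0 <- kinetic_params_4c(0, 1, 1, 1, 0.1, 0.5, 0, 0.2, 0.3)
  expect_equal(simulate_tac(p0, inp$arterial, inp$portal, hk_sched16)$c,
               rep(0, 16))
  p1 <- kinetic_params_4c(0.8, 1, 1, 1, 0.1, 0.5, 0, 0.2, 0.3)
  p2 <- kinetic_params_4c(1.6, 1, 1, 1, 0.1, 0.5, 0, 0.2, 0.3)
  expect_equal(simulate_tac(p2, inp$arterial, inp$portal, hk_sched16)$c,
               2 * simulate_tac(p1, inp$arterial, inp$portal, hk_sched16)$c,
               tolerance = 1e-12)
})

test_that("states and outputs stay nonnegative for valid parameters", {
  set.seed(11)
  inp <- hk_inputs()
  for (i in 1:10) {
    p <- kinetic_params_4c(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2),
                           runif(1, 0, 2), runif(1, 0, 1), runif(1),
                           runif(1, 0, 0.5), runif(1, 0, 0.5), runif(1, 0, 2))
    x <- simulate_tac(p, inp$arterial, inp$portal, hk_sched17)
    expect_true(all(x$c >= -1e-12))
  }
})

test_that("the reference HCC TAC reproduces its pinned regression values", {
  inp <- hk_inputs()
  x <- simulate_tac(hk_p4_hcc, inp$arterial, inp$portal, hk_sched17)
  pinned <- c(0, 0, 0.05401168, 3.45880034, 9.56287505, 15.64548711,
              20.98852748, 25.29161446, 28.50868355, 30.72589810,
              32.08828406, 32.75740795, 28.94464216, 21.12155490,
              18.28210042, 17.37441562, 25.53982826)
  expect_equal(x$c, pinned, tolerance = 1e-7)
})
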