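mid_params <- c(tau_m = 10, sigma_f = 7.5, sigma_s = 7.5, i_inj = 1,
                alpha_0 = 1, theta_0 = 1)

test_that("the quiescent rhythm generator is a fixed point and drive acts as stated", {
  fx <- cpg_fixed()  # E_s = 0
  st0 <- list(V_e = 0, q_e = 0, V_f = 0, q_f = 0)
  quiet <- c(mid_params[1:3], i_inj = 0, mid_params[5:6])
  st1 <- rg_step(st0, quiet, fx, dt = 1)
  expect_equal(st1, st0, tolerance = 1e-15)
  # from rest, dV/dt = +/- i_inj / tau_m (reciprocal drive), dq/dt = 0
  st2 <- rg_step(st0, mid_params, fx, dt = 1)
  expect_equal(st2$V_e, 1 / 10)
  expect_equal(st2$V_f, -1 / 10)
  expect_equal(st2$q_e, 0)
  expect_error(rg_step(st0, mid_params, fx, dt = -1), "positive")
})

test_that("Euler integration converges to an adaptive-solver reference", {
  skip_if_not_installed("deSolve")
  fx <- cpg_fixed()
  rhs <- function(t, y, p) {
    dV <- -(y[1] - fx$A_f * tanh((p[["sigma_f"]] / fx$A_f) * y[1]) +
              y[2] - p[["i_inj"]]) / p[["tau_m"]]
    dq <- (-y[2] + p[["sigma_s"]] * (y[1] - fx$E_s)) /
      (fx$tau_s_factor * p[["tau_m"]])
    list(c(dV, dq))
  }
  ref <- deSolve::ode(c(V = 0.1, q = 0), c(0, 1000), rhs, mid_params,
                      rtol = 1e-12, atol = 1e-12)
  v_fine <- motorloop:::rg_v_trace(unname(mid_params), fx,
                                   duration = 1000, dt = 5e-4)
  expect_lt(abs(v_fine[length(v_fine)] - ref[2, "V"]), 2e-3)
  # and the oscillation is sustained: late amplitude matches early amplitude
  v <- motorloop:::rg_v_trace(unname(mid_params), fx, duration = 5000, dt = 1)
  amp_early <- diff(range(v[1000:2500]))
  amp_late <- diff(range(v[3500:5000]))
  expect_gt(amp_late, 0.9 * amp_early)
  expect_gt(amp_late, 1)
})

test_that("the movement readout converges at first order in the step size", {
  P <- matrix(rep(unname(mid_params), 4), 6, 4)
  d <- sapply(c(1, 0.5, 0.25), function(dt) {
    max(abs(execute_movement(P, duration = 200, dt = dt) -
              execute_movement(P, duration = 200, dt = dt / 2)))
  })
  expect_true(all(diff(d) < 0))            # refinement shrinks the change
  expect_gt(d[1] / d[3], 3)                # ~first-order contraction
  expect_lt(d[3], 1e-2)                    # converged below 1e-2 rad
})

test_that("activation functions reproduce hand-computed logistic values", {
  fx <- cpg_fixed()
  p <- c(alpha_0 = 1, theta_0 = 0.5)
  # sigmoid centre and hand-evaluated point 1/(1+e^-1)
  expect_equal(pf_activation(0.5, p, fx), 0.5)
  expect_equal(pf_activation(1.5, p, fx), 1 / (1 + exp(-1)), tolerance = 1e-12)
  p0 <- c(alpha_0 = 0, theta_0 = 1.7)
  expect_equal(pf_activation(123, p0, fx), 0.5)  # zero slope
  expect_equal(mn_activation(0.5, fx), 0.5)
  expect_equal(mn_activation(0.7, fx), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(mn_activation(1e6, fx), 1.0)
  # sensory inputs are averaged into the drive with weight normalization
  expect_equal(pf_activation(1, c(alpha_0 = 1, theta_0 = 0), fx,
                             sensory = 1, sensory_weights = 1),
               1 / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("joint angles are a bounded combination of the motor neurons", {
  fx <- cpg_fixed()
  expect_equal(joint_angle(0.4, 0.4, fx), 0)      # symmetric cancellation
  expect_equal(joint_angle(0.5, 0.3, fx), 1.0)    # Amp = 5 times 0.2
  set.seed(15)
  mn <- matrix(runif(40), ncol = 2)
  u <- joint_angle(mn[, 1], mn[, 2], fx)
  expect_true(all(abs(u) <= 5))
})

test_that("parameter clamping projects onto the printed intervals", {
  raw <- c(tau_m = 10, sigma_f = 12, sigma_s = 2, i_inj = 5,
           alpha_0 = -1, theta_0 = 3)
  cl <- clamp_cpg_params(raw)
  expect_equal(unname(cl), c(10, 10, 5, 4, 0.001, 2))
  expect_equal(clamp_cpg_params(c(7, 6, 9, -2, 1, 0.5)),
               c(tau_m = 7, sigma_f = 6, sigma_s = 9, i_inj = -2,
                 alpha_0 = 1, theta_0 = 0.5))
  m <- clamp_cpg_params(matrix(100, 6, 4))
  expect_equal(m[, 1], cpg_param_ranges()$upper)
})

test_that("movement execution is deterministic and respects the excursion bound", {
  set.seed(16)
  rg <- cpg_param_ranges()
  for (i in 1:5) {
    P <- matrix(runif(24, rep(rg$lower, 4), rep(rg$upper, 4)), 6, 4)
    a1 <- execute_movement(P)
    a2 <- execute_movement(P)
    expect_identical(a1, a2)
    expect_true(all(abs(a1) <= 5))
  }
  expect_error(execute_movement(matrix(7, 6, 4), duration = -5), "positive")
})
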