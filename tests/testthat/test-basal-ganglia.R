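test_that("rate neurons settle to their closed-form fixed points", {
  p <- bg_params()
  # isolated neuron relaxes to its baseline; rate is the positive part
  for (B in c(0.7, -0.3)) {
    mp <- 0
    for (i in 1:200) mp <- rate_step(mp, B = B)$mp
    expect_equal(mp, B, tolerance = 1e-6)
    expect_equal(rate_step(mp, B = B)$rate, max(B, 0), tolerance = 1e-6)
  }
  # SNr under unit striatal drive: 1.1 - 0.8 = 0.3
  mp <- 0
  for (i in 1:300) mp <- rate_step(mp, inhibition = p$w_str_snr * 1, B = p$B_snr)$mp
  expect_equal(mp, 0.3, tolerance = 1e-6)
  # thalamus under tonic SNr (rate 1.1): 0.9 - 0.66 = 0.24
  mp <- 0
  for (i in 1:300) mp <- rate_step(mp, inhibition = p$w_snr_thal * 1.1, B = p$B_thalamus)$mp
  expect_equal(mp, 0.24, tolerance = 1e-6)
})

test_that("the resting loop is stationary at its tonic state", {
  p <- bg_params(n_actions = 5, n_premotor = 10, n_cells_per_param = 5,
                 noise_amplitude = 0)
  set.seed(21)
  net <- bg_network(p)
  net <- bg_run(net, NULL, n_ms = 300)
  expect_equal(net$state$mp_snr, rep(1.1, 5), tolerance = 1e-4)
  expect_equal(net$state$mp_thal, rep(0.24, 5), tolerance = 1e-4)
  # resting cortex sits below zero: no channel crosses the selection threshold
  expect_true(all(pmax(net$state$mp_ctx, 0) < p$selection_threshold))
  expect_equal(net$state$da, p$B_DA, tolerance = 1e-6)
})

test_that("the dopamine cell relaxes to the gated prediction-limited level", {
  p <- bg_params()
  da <- 0.5
  for (i in 1:200) da <- dopamine_step(da, P = 0, WDA = 0.3, r_str = 1, p)
  expect_equal(da, 0.1, tolerance = 1e-6)          # gate closed: baseline
  for (i in 1:200) da <- dopamine_step(da, P = 1, WDA = 0, r_str = 1, p)
  expect_equal(da, 1.1, tolerance = 1e-6)          # novel outcome: full burst
  for (i in 1:200) da <- dopamine_step(da, P = 1, WDA = 1, r_str = 1, p)
  expect_equal(da, 0.1, tolerance = 1e-6)          # fully predicted: no burst
})

test_that("corticostriatal plasticity clips anticorrelation and tracks dopamine sign", {
  p <- bg_params()
  W <- matrix(0.2, 3, 2)
  r_pre <- c(1, 0.5, 0); r_post <- c(0.9, 0.1)
  # at baseline dopamine only the normalization acts: weights cannot grow
  W1 <- corticostriatal_update(W, r_pre, r_post, da = p$B_DA, p)
  expect_true(all(W1 <= W))
  # anticorrelated pre/post contributes nothing (positive-part clip)
  W2 <- corticostriatal_update(matrix(0, 3, 2), c(0, 0, 1), c(1, 0),
                               da = p$B_DA + 0.5, p)
  expect_equal(W2[1, 1], 0)  # pre below mean with active post: clipped
  expect_gt(W2[3, 1], 0)     # pre above mean with active post: potentiated
  # correlated pre/post under phasic dopamine potentiates
  W3 <- corticostriatal_update(matrix(0.1, 3, 2), r_pre, r_post,
                               da = p$B_DA + 0.8, p)
  expect_gt(W3[1, 1], 0.1)
  # weights never go negative
  W4 <- corticostriatal_update(matrix(1e-6, 3, 2), r_pre, r_post, da = p$B_DA, p)
  expect_true(all(W4 >= 0))
})

test_that("striatum-to-dopamine weights grow only for above-mean cells under phasic dopamine", {
  p <- bg_params()
  w0 <- c(0.1, 0.1)
  expect_equal(da_weight_update(w0, c(1, 0), r_pre_mean = 0.2, da = p$B_DA, p), w0)
  w1 <- da_weight_update(w0, c(1, 0.1), r_pre_mean = 0.2, da = p$B_DA + 1, p)
  expect_gt(w1[1], w0[1])
  expect_equal(w1[2], w0[2])  # below threshold: unchanged
})

test_that("goal encoding is a radial Gaussian over preferred positions", {
  p <- bg_params(n_actions = 3, n_premotor = 4, n_cells_per_param = 5)
  set.seed(22)
  net <- bg_network(p)
  net$premotor_positions <- rbind(c(0.1, 0, 0), c(0.1, 0, 0),
                                  c(0.4, 0, 0), c(5, 5, 5))
  b <- encode_goal(c(0.1, 0, 0), net)
  expect_equal(b[1], 1)
  expect_equal(b[1], b[2])              # equidistant cells encode equally
  expect_lt(b[4], 1e-10)                # far cell silent
  expect_true(all(diff(b[c(4, 3, 1)]) > 0))
})

test_that("action selection clamps exactly one channel and falls back to random", {
  m <- unit_model(seed = 3)
  net <- bg_settle(m$bg)
  set.seed(23)
  goal <- c(-0.3, 0.1, 0)
  sel <- select_action(net, goal)
  expect_true(sel$random)               # untrained weights: random branch
  expect_equal(sum(sel$net$last_r_ctx == 1), 1L)
  expect_equal(which.max(sel$net$last_r_ctx), sel$action)
  expect_true(all(sel$net$last_r_ctx[-sel$action] == 0))
  sel2 <- select_action(net, goal, force_random = TRUE)
  expect_true(sel2$random)
})

test_that("decoding is a clamped population-vector readout", {
  m <- unit_model(seed = 4)
  net <- m$bg
  lib <- net$lib
  # all activity on one cell: that cell's preferred value
  net$state$mp_par <- numeric(length(lib$preferred))
  idx <- which(lib$population == 1L)
  net$state$mp_par[idx[3]] <- 2
  P <- suppressWarnings(decode_parameters(net))  # other populations silent
  expect_equal(P[1, 1], lib$preferred[idx[3]])
  # uniform activity: the mean preferred value (the interval midpoint)
  net$state$mp_par <- rep(1, length(lib$preferred))
  P <- decode_parameters(net)
  rg <- cpg_param_ranges()
  expect_equal(unname(P[, 1]), (rg$lower + rg$upper) / 2, tolerance = 1e-10)
  # silent population decodes to the midpoint with a warning
  net$state$mp_par <- rep(-1, length(lib$preferred))
  expect_warning(P <- decode_parameters(net), "silent")
  expect_equal(unname(P[, 2]), (rg$lower + rg$upper) / 2, tolerance = 1e-10)
})

test_that("repeating an outcome shrinks the phasic dopamine burst (novelty)", {
  p <- bg_params(n_actions = 4, n_premotor = 40, n_cells_per_param = 5)
  set.seed(25)
  net <- bg_network(p)
  outcome <- net$premotor_positions[1, ]
  peaks <- numeric(4)
  for (k in 1:4) {
    net <- bg_settle(net)
    net <- bg_run(net, encode_goal(outcome, net), n_ms = 200, clamp = 2)
    net <- learn_trial(net, outcome, action = 2)
    peaks[k] <- net$last_peak_da
  }
  expect_gt(peaks[1], 0.8)             # first execution: near-full burst
  expect_true(all(diff(peaks) < 1e-8)) # non-increasing with repetition
  expect_lt(peaks[2], 0.5 * peaks[1])  # familiar outcome: collapsed burst
  expect_true(all(net$W >= 0))
  expect_true(all(net$WDA >= 0))
})

test_that("act-and-sense pretraining binds outcomes to their producing actions", {
  cfg <- motorloop_config(bg = list(n_actions = 10, n_premotor = 120,
                                    n_cells_per_param = 11))
  m <- motor_model("unit", seed = 6, config = cfg)
  m <- pretrain_bg(m, max_trials = 200, min_trials = 40)
  net <- m$bg
  # presenting the outcome an action produces re-selects mostly that action
  hits <- 0L
  for (a in 1:10) {
    n2 <- bg_settle(net)
    n2 <- bg_run(n2, NULL, n_ms = 150, clamp = a)
    out <- motorloop:::fk_one(execute_movement(decode_parameters(n2), m$cpg_fixed))
    sel <- motorloop:::bg_action_for_goal(net, out)
    hits <- hits + (sel$action == a)
  }
  expect_gte(hits, 6L)
})
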