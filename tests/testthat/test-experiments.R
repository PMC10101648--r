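test_that("generated goals are producible and respect the minimum distance", {
  set.seed(41)
  g <- generate_goals(4)
  p0 <- initial_hand_position()
  d <- sqrt((g$x - p0[1])^2 + (g$y - p0[2])^2 + (g$z - p0[3])^2)
  expect_true(all(d >= 0.5))
  # positions are the forward kinematics of the stored source angles
  for (i in 1:4) {
    expect_equal(unname(unlist(g[i, c("x", "y", "z")])),
                 unname(forward_kinematics(unlist(g[i, c("pitch", "yaw", "roll", "elbow")]))),
                 tolerance = 1e-12)
  }
  set.seed(41)
  expect_identical(generate_goals(4), g)   # seeded determinism
  expect_error(generate_goals(3, min_dist = 0.5, max_tries = 3), "budget")
})

test_that("the adaptation schedule encodes the three conditions' event timing", {
  s <- adaptation_schedule("rotation_plus_strategy", baseline_trials = 10,
                           perturbed_trials = 20, instruction_delay = 2,
                           strategy_off_to_rotation_off = 5,
                           washout_trials = 8)
  tr <- s$trials
  expect_equal(nrow(tr), 43L)
  expect_false(any(tr$rotation_on[tr$trial <= 10]))
  expect_true(all(tr$rotation_on[tr$trial > 10 & tr$trial <= 35]))
  expect_false(any(tr$rotation_on[tr$trial > 35]))
  expect_equal(which(tr$instructed)[1], 13L)           # onset + delay + 1
  expect_false(any(tr$instructed[tr$phase %in% c("gap", "washout")]))
  s2 <- adaptation_schedule("strategy", baseline_trials = 10,
                            perturbed_trials = 20, washout_trials = 8)
  expect_false(any(s2$trials$rotation_on))             # never perturbed
  expect_true(any(s2$trials$instructed))
  s3 <- adaptation_schedule("rotation", baseline_trials = 10,
                            perturbed_trials = 20, washout_trials = 8)
  expect_false(any(s3$trials$instructed))
  expect_equal(sum(s3$trials$rotation_on), 20L)        # no gap without strategy
  expect_error(adaptation_schedule("strategy", perturbed_trials = 2,
                                   instruction_delay = 5), "instruction_delay")
})

test_that("the cursor rotation only affects the displayed position, never the arm", {
  m <- unit_model(seed = 7)
  sched <- adaptation_schedule("rotation", baseline_trials = 4,
                               perturbed_trials = 6, washout_trials = 3)
  run <- run_adaptation(m, sched)
  tr <- tidy(run)
  off <- !tr$rotation_on
  expect_equal(tr$displayed_x[off], tr$hand_x[off])
  expect_equal(tr$displayed_z[off], tr$hand_z[off])
  on <- tr$rotation_on
  expect_true(all(abs(tr$displayed_x[on] - tr$hand_x[on]) +
                    abs(tr$displayed_y[on] - tr$hand_y[on]) > 1e-9))
  # the rotation is rigid about the start: distances from p0 are preserved
  p0 <- initial_hand_position()
  dh <- sqrt((tr$hand_x - p0[1])^2 + (tr$hand_y - p0[2])^2 + (tr$hand_z - p0[3])^2)
  dd <- sqrt((tr$displayed_x - p0[1])^2 + (tr$displayed_y - p0[2])^2 +
               (tr$displayed_z - p0[3])^2)
  expect_equal(dd, dh, tolerance = 1e-10)
})

test_that("instruction changes only the motor goal, and ablation shares all other draws", {
  m <- unit_model(seed = 8)
  sched <- adaptation_schedule("rotation_plus_strategy", baseline_trials = 4,
                               perturbed_trials = 6, instruction_delay = 2,
                               strategy_off_to_rotation_off = 2,
                               washout_trials = 2)
  full <- run_adaptation(m, sched)
  abl <- run_adaptation(m, sched, ablate_cerebellum = TRUE)
  tf <- tidy(full); ta <- tidy(abl)
  expect_equal(tf$motor_goal_id[tf$instructed], tf$goal_id[tf$instructed] + 2L)
  expect_equal(tf$motor_goal_id[!tf$instructed], tf$goal_id[!tf$instructed])
  # named streams: the ablated run selects identical actions on identical goals
  expect_identical(ta$action, tf$action)
  expect_identical(abl$goals, full$goals)
  # ablated movements are those of the cached action alone: constant per goal
  expect_equal(length(unique(round(ta$hand_x[ta$motor_goal_id == 1], 10))), 1L)
})

test_that("reaching runs cycle goals, log errors, and expose cached-action parity", {
  m <- unit_model(seed = 9, n_goal_inputs = 2)
  r1 <- run_reaching(m, n_trials = 8, n_goals = 2)
  tr <- tidy(r1)
  expect_equal(tr$goal_id, rep(c(1L, 2L), 4))
  expect_true(all(tr$error >= 0))
  g <- glance(r1)
  expect_equal(g$n_trials, 8L)
  # ablated cerebellum: the error is the fixed basal-ganglia residual
  r2 <- run_reaching(m, n_trials = 6, n_goals = 2, ablate_cerebellum = TRUE)
  e <- tidy(r2)$error
  expect_equal(e[seq(1, 5, by = 2)], rep(e[1], 3), tolerance = 1e-12)
  expect_equal(e[seq(2, 6, by = 2)], rep(e[2], 3), tolerance = 1e-12)
  # cerebellum-only modes run and produce bounded errors
  r3 <- run_reaching(m, n_trials = 4, n_goals = 2, mode = "cerebellum")
  expect_true(all(tidy(r3)$error < 2))
  r4 <- run_reaching(m, n_trials = 4, n_goals = 2, mode = "cerebellum_direct")
  expect_true(all(is.finite(tidy(r4)$error)))
})

test_that("cached and uncached action parameters agree for an untouched network", {
  m <- unit_model(seed = 10, n_goal_inputs = 2)
  set.seed(1)
  goals <- motorloop:::with_stream(m$streams, "goals", function()
    generate_goals(2))$value
  a1 <- motorloop:::with_stream(m$streams, "bg", function()
    motorloop:::bg_action_for_goal(m$bg, motorloop:::goal_positions(goals)[1, ]))$value
  a2 <- motorloop:::with_stream(m$streams, "bg", function()
    motorloop:::bg_action_for_goal(m$bg, motorloop:::goal_positions(goals)[1, ]))$value
  expect_equal(a1$action, a2$action)
  expect_equal(a1$params, a2$params, tolerance = 1e-10)
})

test_that("adaptation speed censors when the error never halves", {
  m <- unit_model(seed = 12)
  sched <- adaptation_schedule("rotation", baseline_trials = 2,
                               perturbed_trials = 12, washout_trials = 2)
  run <- run_adaptation(m, sched)
  # fabricate a flat error trace: speed must censor at the phase length
  run$trials$angular_error[run$trials$phase == "perturbation"] <- 40
  sp <- adaptation_speed(run, window = 4)
  expect_true(sp$censored)
  expect_equal(sp$speed, 12L)
  # fabricate an immediate drop: speed is the window position
  run$trials$angular_error[run$trials$phase == "perturbation"] <- c(rep(40, 4), rep(1, 8))
  sp2 <- adaptation_speed(run, window = 4)
  expect_false(sp2$censored)
  expect_lte(sp2$speed, 9L)
})

test_that("goal-driven act-and-sense training reduces the goal-outcome distance", {
  dec <- vapply(1:3, function(s) {
    cfg <- motorloop_config(bg = list(n_actions = 30))
    m <- motor_model("reduced", seed = s, config = cfg)
    m <- suppressWarnings(pretrain_bg(m, max_trials = 200, min_trials = 300,
                                      explore = "threshold"))
    d <- m$pretraining$distance
    q <- length(d) %/% 4
    mean(d[(length(d) - q + 1):length(d)]) < mean(d[1:q])
  }, logical(1))
  expect_gte(sum(dec), 2)   # distance trend decreases in a majority of runs
})

test_that("a single-goal cerebellum-alone run learns within 300 trials", {
  better <- vapply(1:3, function(s) {
    m <- motor_model("reduced", seed = s, n_goal_inputs = 2)
    r <- run_reaching(m, n_trials = 300, n_goals = 1, mode = "cerebellum")
    e <- tidy(r)$error
    mean(utils::tail(e, 50)) < mean(utils::head(e, 50))
  }, logical(1))
  expect_gte(sum(better), 2)
})
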