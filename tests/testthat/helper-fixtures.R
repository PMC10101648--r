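# Shared fixtures, built lazily and cached for the whole test run.
# Desk-scale adaptation models use the reduced preset with a 60-action
# library and the shortened 30/60/30 schedule.

.fixture_cache <- new.env(parent = emptyenv())

desk_config <- function(n_actions = 60) {
  motorloop_config(
    bg = list(n_actions = n_actions),
    schedule = list(baseline_trials = 30, perturbed_trials = 60,
                    washout_trials = 30))
}

# pretrained adaptation-scale model, cached per seed
desk_model <- function(seed) {
  key <- paste0("desk", seed)
  if (is.null(.fixture_cache[[key]])) {
    m <- motor_model("reduced", seed = seed, n_goal_inputs = 4,
                     config = desk_config())
    .fixture_cache[[key]] <- pretrain_bg(m)
  }
  .fixture_cache[[key]]
}

# rotation-condition run, cached per seed (shared by several checks)
desk_rotation_run <- function(seed) {
  key <- paste0("rot", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- run_adaptation(desk_model(seed), "rotation")
  }
  .fixture_cache[[key]]
}

# tiny unit-preset model marked pretrained (for interface/invariant tests
# where selection quality is irrelevant)
unit_model <- function(seed = 1, n_goal_inputs = 4) {
  m <- motor_model("unit", seed = seed, n_goal_inputs = n_goal_inputs)
  m$pretrained <- TRUE
  m
}

# independent brute-force forward kinematics (homogeneous transforms
# multiplied step by step onto the origin)
fk_oracle <- function(a) {
  rot_y <- function(t) matrix(c(cos(t), 0, -sin(t), 0,
                                sin(t), 0, cos(t), 0,
                                0, -1, 0, 0,
                                0, 0, 0, 1), 4, 4, byrow = TRUE)
  p <- pi / 2
  G01 <- rot_y(a[1])
  G12 <- rot_y(p + a[2]); G12[1, 4] <- 0.05 * cos(p + a[2]); G12[2, 4] <- 0.05 * sin(p + a[2])
  G23 <- matrix(c(cos(p + a[3]), 0, sin(p + a[3]), 0,
                  sin(p + a[3]), 0, -cos(p + a[3]), 0,
                  0, 1, 0, 0.22,
                  0, 0, 0, 1), 4, 4, byrow = TRUE)
  G34 <- matrix(c(cos(p + a[4]), -sin(p + a[4]), 0, 0.16 * cos(p + a[4]),
                  sin(p + a[4]), cos(p + a[4]), 0, 0.16 * sin(p + a[4]),
                  0, 0, 1, 0,
                  0, 0, 0, 1), 4, 4, byrow = TRUE)
  v <- c(0, 0, 0, 1)
  for (G in list(G34, G23, G12, G01)) v <- G %*% v
  v[1:3]
}
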