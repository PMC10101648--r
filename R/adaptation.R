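#' Visuomotor-rotation experiment schedule
#'
#' Trial-indexed events of the adaptation task. After `baseline_trials`
#' unperturbed movements, the cursor rotation (in rotation-bearing
#' conditions) switches on for `perturbed_trials`; in strategy-bearing
#' conditions the explicit instruction (re-aiming at the counter-rotated
#' goal) is given `instruction_delay` trials after perturbation onset and
#' removed at the end of the perturbed phase, with the rotation switched
#' off `strategy_off_to_rotation_off` trials later; `washout_trials`
#' unperturbed trials follow.
#'
#' @param condition `"rotation"`, `"strategy"` or
#'   `"rotation_plus_strategy"`.
#' @param baseline_trials,perturbed_trials,washout_trials Phase lengths.
#' @param instruction_delay Trials between perturbation onset and the
#'   instruction.
#' @param strategy_off_to_rotation_off Trials between instruction removal
#'   and rotation removal.
#' @param rotation_deg Cursor rotation, degrees.
#' @return An `adaptation_schedule`: list with the condition, the
#'   parameters and a `trials` tibble (`trial`, `phase`, `rotation_on`,
#'   `instructed`).
#' @export
adaptation_schedule <- function(condition = c("rotation", "strategy",
                                              "rotation_plus_strategy"),
                                baseline_trials = 100, perturbed_trials = 200,
                                instruction_delay = 2,
                                strategy_off_to_rotation_off = 10,
                                rotation_deg = 45, washout_trials = 90) {
  condition <- match.arg(condition)
  stopifnot(baseline_trials >= 0, perturbed_trials >= 1,
            instruction_delay >= 0, strategy_off_to_rotation_off >= 0,
            washout_trials >= 0)
  has_strategy <- condition != "rotation"
  has_rotation <- condition != "strategy"
  if (has_strategy && instruction_delay >= perturbed_trials)
    stop("`instruction_delay` must be smaller than `perturbed_trials`", call. = FALSE)
  B <- baseline_trials; P <- perturbed_trials
  G <- if (has_strategy) strategy_off_to_rotation_off else 0L
  n <- B + P + G + washout_trials
  trial <- seq_len(n)
  phase <- rep("washout", n)
  phase[trial <= B] <- "baseline"
  phase[trial > B & trial <= B + P] <- "perturbation"
  if (G > 0) phase[trial > B + P & trial <= B + P + G] <- "gap"
  rotation_on <- has_rotation & trial > B & trial <= B + P + G
  instructed <- has_strategy & trial > B + instruction_delay & trial <= B + P
  structure(list(condition = condition,
                 baseline_trials = B, perturbed_trials = P,
                 instruction_delay = instruction_delay,
                 strategy_off_to_rotation_off = G,
                 rotation_deg = rotation_deg, washout_trials = washout_trials,
                 trials = tibble::tibble(trial = trial, phase = phase,
                                         rotation_on = rotation_on,
                                         instructed = instructed)),
            class = "adaptation_schedule")
}

# Training-goal pairs for the adaptation task: both goals and (in
# strategy-bearing schedules) their counter-rotated re-aiming targets must
# lie within the model's trained action repertoire, otherwise the baseline
# and instructed movements are dominated by repertoire gaps rather than by
# the perturbation. Coverage = distance to the nearest recorded action
# outcome.
sample_adaptation_goals <- function(model, schedule, max_pairs = 60L,
                                    competence_deg = model$config$goals$competence_deg) {
  cfg <- model$config$goals
  p0 <- initial_hand_position(model$cpg_fixed)
  rot <- schedule$rotation_deg * pi / 180
  needs_counter <- schedule$condition != "rotation"
  # baseline-competence probe: the model must be able to aim at the target
  # (direction of the selected action's movement within competence_deg of
  # the target direction), mirroring the baseline-competence requirement
  # of the human protocol
  probe <- function(target, slot) {
    act <- bg_action_for_goal(model$bg, target)
    # the baseline movement includes the (initially biased) cerebellar
    # contribution for this goal-input slot, so probe with it too
    cb <- run_trial(model$cerebellum, slot, perturb = FALSE)$output
    pars <- map_cerebellar_output(cb * model$cerebellum$params$output_gain,
                                  "additive", base = act$params)
    out <- fk_one(execute_movement(pars, model$cpg_fixed,
                                   duration = model$config$cpg$duration,
                                   dt = model$config$cpg$dt,
                                   readout_ms = model$config$cpg$readout_ms))
    u <- out - p0; v <- target - p0
    ang <- acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    screened <- !is.null(model$action_outcomes)
    list(ok = !screened || ang <= competence_deg,
         cache = list(action = act$action, params = act$params))
  }
  draw_one <- function(slot) {
    for (i in seq_len(max_pairs)) {
      g <- generate_goals(1L, min_dist = cfg$min_dist,
                          fixed = model$cpg_fixed, max_tries = cfg$max_tries)
      pr <- probe(unlist(g[1, c("x", "y", "z")]), slot)
      if (pr$ok) return(list(g = g, cache = pr$cache))
    }
    NULL
  }
  for (i in seq_len(max_pairs)) {
    d1 <- draw_one(1L); d2 <- draw_one(2L)
    if (is.null(d1) || is.null(d2)) break
    pair <- dplyr::bind_rows(d1$g, d2$g)
    pair$id <- 1:2
    gp <- goal_positions(pair)
    axis <- cross3(gp[1L, ], gp[2L, ])
    if (sqrt(sum(axis^2)) < 1e-6) next
    cache <- list(d1$cache, d2$cache)
    if (!needs_counter) return(list(goals = pair, cache = cache))
    axis <- axis / sqrt(sum(axis^2))
    pc <- lapply(1:2, function(k) {
      probe(p0 + rotate_endpoint(gp[k, ] - p0, axis, -rot), 2L + k)
    })
    if (all(vapply(pc, `[[`, logical(1L), "ok"))) {
      return(list(goals = pair, cache = c(cache, lapply(pc, `[[`, "cache"))))
    }
  }
  if (competence_deg < 90) {
    # a sparse or poorly converged repertoire: relax the screen rather
    # than fail, and say so
    warning("relaxing the baseline-competence screen to ",
            round(competence_deg * 2), " degrees", call. = FALSE)
    return(sample_adaptation_goals(model, schedule, max_pairs,
                                   competence_deg = competence_deg * 2))
  }
  stop("could not find a goal pair whose re-aiming targets the action ",
       "repertoire can reach", call. = FALSE)
}

# schedule matching a model's config section
schedule_from_config <- function(model, condition) {
  s <- model$config$schedule
  adaptation_schedule(condition,
                      baseline_trials = s$baseline_trials,
                      perturbed_trials = s$perturbed_trials,
                      instruction_delay = s$instruction_delay,
                      strategy_off_to_rotation_off = s$strategy_off_to_rotation_off,
                      rotation_deg = s$rotation_deg,
                      washout_trials = s$washout_trials)
}

#' Run the visuomotor-rotation adaptation task
#'
#' Implements the three-condition protocol on two training goals. The
#' cursor rotation turns the *displayed* endpoint about the axis given by
#' the cross product of the two goal positions, anchored at the initial
#' hand position; the physical arm is never touched. The explicit
#' instruction replaces the motor goal by the counter-rotated goal (a
#' distinct cerebellar goal input with its own error baseline). Cerebellar
#' learning always uses the aiming error -- the distance between the
#' displayed endpoint and the *current motor goal* -- never the task
#' error, which is what produces the drift under instruction and the
#' aftereffects.
#'
#' By default the concrete action for each motor goal is computed once
#' after pretraining and cached (the published speed-up); with
#' `cached_actions = FALSE` the full loop (selection plus novelty learning
#' on the displayed outcome) is simulated every trial.
#'
#' @param model Pretrained [motor_model()] with at least four cerebellar
#'   goal inputs.
#' @param schedule [adaptation_schedule()]; built from the model config
#'   (reduced presets shorten it) if a condition string is given.
#' @param goals Two-row goal tibble; generated from the model's goal
#'   stream if `NULL`.
#' @param ablate_cerebellum Remove the cerebellar contribution (the
#'   no-cerebellum control); the reservoir stream is left untouched so
#'   ablated and intact runs share all other randomness.
#' @param cached_actions See above.
#' @return An `adaptation_run` with a `trials` tibble: `trial`, `phase`,
#'   `rotation_on`, `instructed`, `goal_id`, `motor_goal_id`, `action`,
#'   the hand and displayed (cursor) positions,
#'   `error_aim` (Euclidean, drives the cerebellum), `angular_error`
#'   (signed, vs the task goal), `angular_error_aim` (signed, vs the motor
#'   goal), `peak_da`.
#' @export
run_adaptation <- function(model, schedule = "rotation", goals = NULL,
                           ablate_cerebellum = FALSE, cached_actions = TRUE) {
  if (is.character(schedule)) schedule <- schedule_from_config(model, schedule)
  stopifnot(inherits(schedule, "adaptation_schedule"))
  if (!model$pretrained)
    stop("run_adaptation() requires a pretrained model; run pretrain_bg() first",
         call. = FALSE)
  st <- model$streams
  probe_cache <- NULL
  if (is.null(goals)) {
    res <- with_stream(st, "goals", function() {
      sample_adaptation_goals(model, schedule)
    })
    st <- res$streams
    goals <- res$value$goals
    probe_cache <- res$value$cache
  }
  stopifnot(nrow(goals) == 2L)
  has_strategy <- schedule$condition != "rotation"
  if (model$cerebellum$n_goals < (if (has_strategy) 4L else 2L))
    stop("the reservoir needs one goal-input cell per motor goal ",
         "(4 for strategy-bearing conditions)", call. = FALSE)
  gp <- goal_positions(goals)
  p0 <- initial_hand_position(model$cpg_fixed)
  axis <- cross3(gp[1L, ], gp[2L, ])
  if (sqrt(sum(axis^2)) < 1e-12)
    stop("degenerate rotation axis: the two goal positions are collinear", call. = FALSE)
  axis <- axis / sqrt(sum(axis^2))
  rot <- schedule$rotation_deg * pi / 180
  # motor-goal positions: ids 1-2 task goals, 3-4 their counter-rotations
  counter <- t(vapply(1:2, function(g) {
    p0 + rotate_endpoint(gp[g, ] - p0, axis, -rot)
  }, numeric(3L)))
  motor_pos <- rbind(gp, counter)

  net <- model$bg
  cere <- model$cerebellum
  n_motor <- if (has_strategy) 4L else 2L
  cache <- vector("list", n_motor)
  if (cached_actions && !is.null(probe_cache)) {
    cache <- probe_cache          # reuse the goal-screening selections
  } else if (cached_actions) {
    res <- with_stream(st, "bg", function() {
      out <- vector("list", n_motor)
      for (g in seq_len(n_motor)) {
        act <- bg_action_for_goal(net, motor_pos[g, ])
        out[[g]] <- list(action = act$action, params = act$params)
        net <- act$net
      }
      list(net = net, cache = out)
    })
    st <- res$streams
    net <- res$value$net
    cache <- res$value$cache
  }
  sched <- schedule$trials
  n <- nrow(sched)
  rows <- vector("list", n)
  for (tr in seq_len(n)) {
    gid <- (tr - 1L) %% 2L + 1L
    mid <- if (sched$instructed[[tr]]) 2L + gid else gid
    output <- numeric(cere$params$n_outputs)
    if (!ablate_cerebellum) {
      res <- with_stream(st, "cerebellum", function() run_trial(cere, mid))
      st <- res$streams
      cere <- res$value$res
      output <- res$value$output
    }
    peak_da <- NA_real_
    if (cached_actions) {
      base <- cache[[mid]]$params
      action <- cache[[mid]]$action
    } else {
      res <- with_stream(st, "bg", function() bg_action_for_goal(net, motor_pos[mid, ]))
      st <- res$streams
      base <- res$value$params
      action <- res$value$action
      net <- res$value$net
    }
    params <- map_cerebellar_output(output * cere$params$output_gain,
                                      "additive", base = base)
    mv <- model_execute(model, params)
    displayed <- if (sched$rotation_on[[tr]]) {
      p0 + rotate_endpoint(mv$position - p0, axis, rot)
    } else mv$position
    E_aim <- sqrt(sum((displayed - motor_pos[mid, ])^2))
    if (!ablate_cerebellum) cere <- apply_learning(cere, mid, E_aim)
    if (!cached_actions) {
      res <- with_stream(st, "bg", function() learn_trial(net, displayed, action))
      st <- res$streams
      net <- res$value
      peak_da <- net$last_peak_da
    }
    rows[[tr]] <- tibble::tibble(
      trial = tr, phase = sched$phase[[tr]],
      rotation_on = sched$rotation_on[[tr]],
      instructed = sched$instructed[[tr]],
      goal_id = gid, motor_goal_id = mid, action = action,
      hand_x = mv$position[[1L]], hand_y = mv$position[[2L]],
      hand_z = mv$position[[3L]],
      displayed_x = displayed[[1L]], displayed_y = displayed[[2L]],
      displayed_z = displayed[[3L]],
      error_aim = E_aim,
      angular_error = angular_error(p0, displayed, gp[gid, ], axis),
      angular_error_aim = angular_error(p0, displayed, motor_pos[mid, ], axis),
      peak_da = peak_da)
  }
  model$bg <- net
  model$cerebellum <- cere
  model$streams <- st
  structure(list(trials = dplyr::bind_rows(rows), schedule = schedule,
                 goals = goals, axis = axis,
                 ablate_cerebellum = ablate_cerebellum,
                 cached_actions = cached_actions, model = model),
            class = "adaptation_run")
}

#' @export
print.adaptation_run <- function(x, ...) {
  tr <- x$trials
  cat("<adaptation_run>", x$schedule$condition,
      if (x$ablate_cerebellum) "(cerebellum ablated)", "\n")
  for (ph in unique(tr$phase)) {
    cat(sprintf("  %-12s %3d trials  mean |angular error| %6.1f deg\n",
                ph, sum(tr$phase == ph),
                mean(abs(tr$angular_error[tr$phase == ph]))))
  }
  invisible(x)
}

#' Trials-to-half-error adaptation speed
#'
#' Number of perturbed trials until the moving average (window `window`)
#' of the absolute task angular error first falls below half of its value
#' at perturbation onset (the mean over the first window of perturbed
#' trials). Censored at the number of perturbed trials when the error
#' never halves.
#'
#' @param run An `adaptation_run`.
#' @param window Moving-average window, trials.
#' @return List with `speed` (trials), `censored` (logical) and
#'   `reference` (the onset error level, degrees).
#' @export
adaptation_speed <- function(run, window = 10) {
  tr <- run$trials
  err <- abs(tr$angular_error[tr$phase == "perturbation"])
  n <- length(err)
  stopifnot(n >= window)
  ref <- mean(err[seq_len(window)])
  ma <- stats::filter(err, rep(1 / window, window), sides = 1)
  hit <- which(!is.na(ma) & ma < ref / 2)
  if (length(hit) == 0L) {
    list(speed = n, censored = TRUE, reference = ref)
  } else {
    list(speed = hit[[1L]], censored = FALSE, reference = ref)
  }
}

#' Sweep perturbation variability against adaptation speed
#'
#' Reruns the rotation-condition adaptation task over grids of
#' perturbation amplitude `A` and frequency `f` (one factor varied at a
#' time, the other at its model default), with a fresh pretrained model
#' per seed shared across the grid. Higher motor variability is expected
#' to speed adaptation up to a saturating noise level.
#'
#' @param seeds Integer seeds (one model per seed).
#' @param amplitudes,frequencies Grids for `A` and `f`; either may be
#'   `NULL` to skip that factor.
#' @param preset,config Passed to [motor_model()].
#' @param schedule An [adaptation_schedule()] or condition string.
#' @return A `variability_sweep`: tibble with `factor`, `value`, `seed`,
#'   `speed`, `censored`.
#' @export
run_variability_sweep <- function(seeds = 1:5, amplitudes = c(5, 20, 35),
                                  frequencies = c(1, 9, 17),
                                  preset = "reduced", config = NULL,
                                  schedule = "rotation") {
  rows <- list()
  for (seed in seeds) {
    base <- motor_model(preset, seed = seed, n_goal_inputs = 4L, config = config)
    base <- pretrain_bg(base)
    run_one <- function(factor, value) {
      m <- base
      if (factor == "amplitude") m$cerebellum$params$A <- value
      if (factor == "frequency") m$cerebellum$params$f <- value
      run <- run_adaptation(m, schedule = schedule)
      sp <- adaptation_speed(run)
      tibble::tibble(factor = factor, value = value, seed = seed,
                     speed = sp$speed, censored = sp$censored)
    }
    for (A in amplitudes %||% numeric()) rows[[length(rows) + 1L]] <- run_one("amplitude", A)
    for (f in frequencies %||% numeric()) rows[[length(rows) + 1L]] <- run_one("frequency", f)
  }
  structure(dplyr::bind_rows(rows), class = c("variability_sweep", class(tibble::tibble())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
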