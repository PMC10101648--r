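#' Sample reachable goals
#'
#' Goals are generated by drawing a random concrete-action parameter set
#' (uniform over the clamp intervals), executing it through the CPGs and
#' keeping the resulting hand position, so every goal is reachable by
#' construction -- not merely inside the arm's workspace but actually
#' producible by some motor program, which is what gives the learning
#' problem a solution. Only goals at least `min_dist` from the initial
#' hand position are kept, avoiding very short movements. Uses the
#' current RNG state.
#'
#' @param n Number of goals.
#' @param min_dist Minimum distance from the initial hand position.
#' @param fixed [cpg_fixed()] (for the reference configuration).
#' @param max_tries Sampling budget; exceeding it is an error.
#' @return Tibble with columns `id`, `x`, `y`, `z` and the source joint
#'   angles `pitch`, `yaw`, `roll`, `elbow`.
#' @export
generate_goals <- function(n, min_dist = 0.5,
                           fixed = cpg_fixed(), max_tries = 10000) {
  stopifnot(n >= 1)
  p0 <- initial_hand_position(fixed)
  rg <- cpg_param_ranges()
  rows <- vector("list", n)
  found <- 0L
  for (i in seq_len(max_tries)) {
    pars <- matrix(stats::runif(24L, rep(rg$lower, 4L), rep(rg$upper, 4L)), 6L, 4L)
    ang <- execute_movement(pars, fixed)
    pos <- fk_one(ang)
    if (sqrt(sum((pos - p0)^2)) >= min_dist) {
      found <- found + 1L
      rows[[found]] <- c(pos, ang)
      if (found == n) break
    }
  }
  if (found < n) {
    stop("goal generation failed: sampling budget exhausted (", max_tries,
         " tries for ", n, " goals at min_dist ", min_dist, ")", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  tibble::tibble(id = seq_len(n), x = m[, 1L], y = m[, 2L], z = m[, 3L],
                 pitch = m[, 4L], yaw = m[, 5L], roll = m[, 6L],
                 elbow = m[, 7L])
}

goal_positions <- function(goals) {
  unname(as.matrix(goals[, c("x", "y", "z")]))
}

# Select an action for a goal and decode its parameters (settled network).
bg_action_for_goal <- function(net, goal, force_random = FALSE) {
  net <- bg_settle(net)
  sel <- select_action(net, goal, force_random = force_random)
  params <- decode_parameters(sel$net)
  list(net = sel$net, action = sel$action, params = params,
       random = sel$random, max_ctx = sel$max_ctx)
}

#' Pretrain the basal ganglia by act-and-sense exploration
#'
#' Loops the act-and-sense trial: settle, present a random goal, select an
#' action (random when the motor cortex stays sub-threshold), execute it,
#' and then learn on the *achieved* outcome, binding the outcome to the
#' action that produced it. After `min_trials`, each trial additionally
#' probes the map with a randomly chosen past outcome; training stops once
#' the producing action is re-selected on `probe_successes` consecutive
#' probes. The trace of goal-to-outcome distances is kept (the act-and-
#' sense learning curve).
#'
#' @param model [motor_model()].
#' @param max_trials Trial budget; if exhausted without convergence the
#'   partially trained model is returned with a warning.
#' @param probe_successes Consecutive probe successes required to stop.
#' @param min_trials Trials before probes start counting (defaults to
#'   five per action so the library is explored first).
#' @param explore `"random"` activates a random action on every training
#'   trial (the published training block randomly activates the actions,
#'   which gives every action an equal number of clean novelty-gated
#'   bindings); `"threshold"` uses the goal-driven selection rule with its
#'   sub-threshold random branch throughout.
#' @return The model, pretrained, with a `pretraining` tibble
#'   (`trial`, `goal` coordinates, `action`, `random`, `distance`,
#'   `peak_da`).
#' @export
pretrain_bg <- function(model, max_trials = 80L * model$bg$params$n_actions,
                        probe_successes = 3L,
                        min_trials = 5L * model$bg$params$n_actions,
                        explore = c("random", "threshold")) {
  explore <- match.arg(explore)
  net <- model$bg
  outcomes <- list()
  rows <- vector("list", max_trials)
  succ <- 0L
  converged <- FALSE
  n_done <- 0L
  st <- model$streams
  for (tr in seq_len(max_trials)) {
    res <- with_stream(st, "bg", function() {
      rg <- cpg_param_ranges()
      gp <- matrix(stats::runif(24L, rep(rg$lower, 4L), rep(rg$upper, 4L)), 6L, 4L)
      goal <- fk_one(execute_movement(gp, model$cpg_fixed))
      act <- bg_action_for_goal(net, goal, force_random = explore == "random")
      mv <- model_execute(model, act$params)
      net2 <- learn_trial(act$net, mv$position, act$action)
      list(net = net2, goal = goal, action = act$action, random = act$random,
           outcome = mv$position, peak_da = net2$last_peak_da)
    })
    st <- res$streams
    v <- res$value
    net <- v$net
    outcomes[[length(outcomes) + 1L]] <- list(action = v$action, outcome = v$outcome)
    rows[[tr]] <- tibble::tibble(
      trial = tr, action = v$action, random = v$random,
      distance = sqrt(sum((v$goal - v$outcome)^2)), peak_da = v$peak_da)
    n_done <- tr
    if (tr >= min_trials) {
      res <- with_stream(st, "bg", function() {
        probe <- outcomes[[sample.int(length(outcomes), 1L)]]
        sel <- bg_action_for_goal(net, probe$outcome)
        list(net = sel$net, hit = identical(sel$action, probe$action))
      })
      st <- res$streams
      net <- res$value$net
      succ <- if (res$value$hit) succ + 1L else 0L
      if (succ >= probe_successes) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    warning("basal-ganglia pretraining did not converge within ", max_trials,
            " trials; returning the partially trained network", call. = FALSE)
  }
  model$bg <- net
  model$streams <- st
  model$pretrained <- TRUE
  model$pretraining <- dplyr::bind_rows(rows[seq_len(n_done)])
  model$pretraining$converged <- converged
  # deterministic action -> outcome map (first recorded execution of each)
  om <- matrix(NA_real_, model$bg$params$n_actions, 3L)
  for (o in outcomes) if (is.na(om[o$action, 1L])) om[o$action, ] <- o$outcome
  model$action_outcomes <- om
  model
}

#' Run a reaching task
#'
#' Cycles through the goal set for `n_trials` movements. In `"full"` mode
#' the pretrained basal ganglia supply a concrete action per goal (cached
#' once per goal by default, reproducing the published speed-up) and the
#' cerebellum adds graded corrections; in `"cerebellum"` mode the reservoir
#' output alone is mapped affinely onto the CPG parameter intervals; in
#' `"cerebellum_direct"` mode the first four outputs are read directly as
#' joint angles (no CPGs). Cerebellar learning uses the Euclidean distance
#' between the goal and the achieved hand position.
#'
#' @param model [motor_model()] (pretrained for `"full"` mode).
#' @param n_trials Number of movements.
#' @param goals Goal tibble from [generate_goals()]; generated from the
#'   model's goal stream if `NULL`.
#' @param n_goals Number of goals to generate when `goals` is `NULL`.
#' @param mode Task mode, see above.
#' @param cached_actions Cache the selected action per goal (full mode).
#' @param ablate_cerebellum Drop the cerebellar contribution entirely.
#' @return A `reaching_run` object with a `trials` tibble (`trial`,
#'   `goal_id`, `action`, `error`, `output_norm`, `e_bar`), the goal set
#'   and the updated model.
#' @export
run_reaching <- function(model, n_trials, goals = NULL, n_goals = 8,
                         mode = c("full", "cerebellum", "cerebellum_direct"),
                         cached_actions = TRUE, ablate_cerebellum = FALSE) {
  mode <- match.arg(mode)
  st <- model$streams
  if (is.null(goals)) {
    res <- with_stream(st, "goals", function() {
      generate_goals(n_goals, min_dist = model$config$goals$min_dist,
                     fixed = model$cpg_fixed,
                     max_tries = model$config$goals$max_tries)
    })
    st <- res$streams
    goals <- res$value
  }
  gp <- goal_positions(goals)
  n_goals <- nrow(goals)
  if (n_goals > model$cerebellum$n_goals && mode != "full") {
    stop("the reservoir has ", model$cerebellum$n_goals,
         " goal-input cells but ", n_goals, " goals were supplied", call. = FALSE)
  }
  net <- model$bg
  cere <- model$cerebellum
  cache <- vector("list", n_goals)
  if (mode == "full") {
    if (!model$pretrained)
      stop("full-model reaching requires a pretrained model; run pretrain_bg() first",
           call. = FALSE)
    if (cached_actions) {
      res <- with_stream(st, "bg", function() {
        out <- vector("list", n_goals)
        for (g in seq_len(n_goals)) {
          act <- bg_action_for_goal(net, gp[g, ])
          out[[g]] <- list(action = act$action, params = act$params)
          net <- act$net
        }
        list(net = net, cache = out)
      })
      st <- res$streams
      net <- res$value$net
      cache <- res$value$cache
    }
  }
  rows <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    gid <- (tr - 1L) %% n_goals + 1L
    action <- NA_integer_
    output <- numeric(cere$params$n_outputs)
    if (!ablate_cerebellum) {
      res <- with_stream(st, "cerebellum", function() run_trial(cere, gid))
      st <- res$streams
      cere <- res$value$res
      output <- res$value$output
    }
    if (mode == "full") {
      if (cached_actions) {
        base <- cache[[gid]]$params
        action <- cache[[gid]]$action
      } else {
        res <- with_stream(st, "bg", function() bg_action_for_goal(net, gp[gid, ]))
        st <- res$streams
        base <- res$value$params
        action <- res$value$action
        net <- res$value$net
      }
      params <- map_cerebellar_output(output * cere$params$output_gain,
                                      "additive", base = base)
      mv <- model_execute(model, params)
    } else if (mode == "cerebellum") {
      params <- map_cerebellar_output(output, "affine")
      mv <- model_execute(model, params)
    } else {
      ang <- map_cerebellar_output(output, "angles", fixed = model$cpg_fixed)
      mv <- list(angles = ang, position = fk_one(ang))
    }
    E <- sqrt(sum((mv$position - gp[gid, ])^2))
    if (!ablate_cerebellum) {
      cere <- apply_learning(cere, gid, E)
    }
    if (mode == "full" && !cached_actions) {
      res <- with_stream(st, "bg", function() learn_trial(net, mv$position, action))
      st <- res$streams
      net <- res$value
    }
    rows[[tr]] <- tibble::tibble(trial = tr, goal_id = gid, action = action,
                                 error = E,
                                 output_norm = sqrt(sum(output^2)),
                                 e_bar = cere$Ebar[[gid]])
  }
  model$bg <- net
  model$cerebellum <- cere
  model$streams <- st
  structure(list(trials = dplyr::bind_rows(rows), goals = goals, mode = mode,
                 cached_actions = cached_actions,
                 ablate_cerebellum = ablate_cerebellum, model = model),
            class = "reaching_run")
}

#' @export
print.reaching_run <- function(x, ...) {
  n <- nrow(x$trials)
  w <- min(50L, n)
  cat("<reaching_run>", x$mode, "mode,", n, "trials,", nrow(x$goals), "goals\n")
  cat(sprintf("  mean error: first %d trials %.3f, last %d trials %.3f\n",
              w, mean(x$trials$error[seq_len(w)]),
              w, mean(x$trials$error[seq(n - w + 1L, n)])))
  invisible(x)
}
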