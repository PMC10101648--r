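#' Cerebellar reservoir parameters
#'
#' The cerebellum is a 400-unit randomly connected recurrent network
#' (rates `tanh(x)`); 24 of the units are output cells whose mean activity
#' after the goal input is switched off is read out as additive corrections
#' to the CPG parameters. Learning is node perturbation: `f` is the
#' network-wide perturbation rate (events per second), so at every step
#' each unit is independently kicked with probability `f dt / (1000 N)` by
#' an additive draw from Uniform(-A, A) -- a few, large, single-neuron
#' kicks per trial, which keeps the credit assignment of each kick clean;
#' a cubic
#' eligibility trace marks which synapses carried the perturbation, and at
#' the end of a trial weights move along the trace when the aiming error
#' improved on its per-goal running mean.
#'
#' Because the trace cubes the post-synaptic deviation, raw updates span
#' many orders of magnitude; each synapse's per-trial change is therefore
#' capped at `delta_max` (the cube then acts as a soft selector of
#' perturbed synapses), and weights are clipped to `weight_cap` to guard
#' against numerical blow-up in the documented unstable regimes.
#'
#' @param n_units Reservoir size.
#' @param n_outputs Number of output cells (six CPG parameters x 4 joints).
#' @param tau Membrane time constant, ms.
#' @param f Perturbation frequency, events per second across the network.
#' @param A Perturbation amplitude.
#' @param eta Learning rate of the weight update.
#' @param input_weight_range Goal-input weights drawn from
#'   Uniform(-range, range).
#' @param init_weight_sd Standard deviation of the initial recurrent
#'   weights.
#' @param x_init_range Trial-start activations drawn from
#'   Uniform(-range, range).
#' @param xbar_tau Time constant of the running activation average, ms.
#' @param ebar_coef Coefficient of the per-goal error EMA
#'   (`Ebar <- (1 - c) Ebar + c E`).
#' @param weight_cap Hard bound on |J| entries.
#' @param delta_max Per-synapse, per-trial cap on |dJ| (calibrated).
#' @param dt Integration step, ms.
#' @param input_ms,free_ms Durations of the input-on and input-off phases
#'   of a trial.
#' @param output_gain Scale of the additive corrections in the full model,
#'   as a fraction of each parameter's half clamp width (calibrated): it
#'   sets both the reach of the cerebellar fine-tuning and the movement
#'   noise that perturbation events inject.
#' @return A list of class `reservoir_params`.
#' @export
reservoir_params <- function(n_units = 400, n_outputs = 24, tau = 10,
                             f = 9, A = 20, eta = 0.8,
                             input_weight_range = 0.2, init_weight_sd = 0.05,
                             x_init_range = 0.01, xbar_tau = 5,
                             ebar_coef = 0.2, weight_cap = 1,
                             delta_max = 1e-3, dt = 1,
                             input_ms = 200, free_ms = 200,
                             output_gain = 0.25) {
  stopifnot(f >= 0, A >= 0, eta >= 0, n_outputs <= n_units)
  structure(as.list(environment()), class = "reservoir_params")
}

#' Build a fresh cerebellar reservoir
#'
#' Recurrent weights `J` are drawn N(0, `init_weight_sd`); goal-input
#' weights `B` (one column per goal-input cell) are Uniform in
#' plus/minus `input_weight_range`. Per-goal error baselines start
#' unobserved. Uses the current RNG state.
#'
#' @param params [reservoir_params()].
#' @param n_goals Number of goal-input cells (one per distinct motor goal,
#'   instructed goals included).
#' @return A list of class `reservoir`.
#' @export
reservoir <- function(params = reservoir_params(), n_goals = 2) {
  N <- params$n_units
  structure(list(params = params,
                 J = matrix(stats::rnorm(N * N, 0, params$init_weight_sd), N, N),
                 B = matrix(stats::runif(N * n_goals, -params$input_weight_range,
                                         params$input_weight_range), N, n_goals),
                 n_goals = n_goals,
                 Ebar = rep(NA_real_, n_goals),
                 elig = NULL),
            class = "reservoir")
}

#' Run one cerebellar trial
#'
#' Activations start at a small uniform random value; the goal-input cell
#' is active for `input_ms`, then silent for `free_ms`; the output is the
#' mean rate of the output cells over the silent phase. Perturbations and
#' the eligibility trace accumulate throughout; the trace is stored on the
#' returned reservoir for a subsequent [apply_learning()] call. Uses the
#' current RNG state.
#'
#' @param res [reservoir()].
#' @param goal_id Goal-input index (1-based), or `NA` for no input.
#' @param perturb Set `FALSE` to disable perturbations (A = 0) for this
#'   trial.
#' @return List with updated `res` and `output` (length `n_outputs`,
#'   bounded in (-1, 1)).
#' @export
run_trial <- function(res, goal_id, perturb = TRUE) {
  p <- res$params
  out <- cpp_reservoir_trial(res$J, res$B,
                             if (is.na(goal_id)) -1L else goal_id - 1L,
                             p$n_outputs,
                             as.integer(round(p$input_ms / p$dt)),
                             as.integer(round(p$free_ms / p$dt)),
                             p$dt, p$tau,
                             if (perturb) p$f / p$n_units else 0, p$A,
                             p$xbar_tau, p$x_init_range)
  res$elig <- out$elig
  list(res = res, output = as.numeric(out$output))
}

#' Apply the perturbation-learning weight update
#'
#' `dJ = -eta * e * Ebar * (E - Ebar)` with the per-goal running mean
#' error `Ebar`: perturbations whose eligibility coincides with an error
#' below the running mean are reinforced. Each element of `dJ` is capped at
#' `delta_max` in magnitude and `J` clipped to `weight_cap`; `Ebar` is then
#' updated with the observed error (initialized to the first observation).
#'
#' @param res [reservoir()] holding the trace of the trial just run.
#' @param goal_id Goal whose baseline is used and updated.
#' @param E Observed aiming error (non-negative Euclidean distance).
#' @return Updated reservoir.
#' @export
apply_learning <- function(res, goal_id, E) {
  stopifnot(!is.null(res$elig), E >= 0)
  p <- res$params
  eb <- res$Ebar[[goal_id]]
  if (is.na(eb)) eb <- E
  dJ <- -p$eta * res$elig * eb * (E - eb)
  dJ[dJ > p$delta_max] <- p$delta_max
  dJ[dJ < -p$delta_max] <- -p$delta_max
  J <- res$J + dJ
  J[J > p$weight_cap] <- p$weight_cap
  J[J < -p$weight_cap] <- -p$weight_cap
  res$J <- J
  res$Ebar[[goal_id]] <- (1 - p$ebar_coef) * eb + p$ebar_coef * E
  res$elig <- NULL
  res
}

#' Single reservoir step (reference implementation)
#'
#' One Euler step of the leaky recurrent dynamics, followed by optional
#' perturbation draws, the running-average update and the rate
#' nonlinearity. Exposed for property tests; the trial loop itself runs in
#' compiled code with identical ordering.
#'
#' @param state List with `x`, `x_bar`, `r`.
#' @param J Recurrent weight matrix.
#' @param input Input current vector (e.g. `B[, goal]` or 0).
#' @param params [reservoir_params()].
#' @param perturb Apply the perturbation draws.
#' @return Updated state list.
#' @export
reservoir_step <- function(state, J, input = 0, params = reservoir_params(),
                           perturb = TRUE) {
  x <- state$x + params$dt / params$tau *
    (-state$x + as.numeric(J %*% state$r) + input)
  if (perturb && params$f > 0 && params$A > 0) {
    hit <- stats::runif(length(x)) <
      params$f * params$dt / (1000 * params$n_units)
    if (any(hit)) x[hit] <- x[hit] + stats::runif(sum(hit), -params$A, params$A)
  }
  x_bar <- state$x_bar + params$dt / params$xbar_tau * (x - state$x_bar)
  # the trace uses the deviation from the average *before* this update
  list(x = x, x_bar_prev = state$x_bar, x_bar = x_bar, r = tanh(x))
}

#' Cubic eligibility-trace increment (reference implementation)
#'
#' `e_ij <- e_ij + (r_j(t-1) * (x_i(t) - x_bar_i))^3`: the cube makes the
#' trace supralinear, so the large post-synaptic deviations caused by
#' perturbation events dominate ordinary fluctuations.
#'
#' @param e Trace matrix (post x pre).
#' @param r_prev Previous-step rates (pre-synaptic).
#' @param x Current activations (post-synaptic).
#' @param x_bar Running-average activations.
#' @return Updated trace matrix.
#' @export
update_traces <- function(e, r_prev, x, x_bar) {
  e + outer((x - x_bar)^3, r_prev^3)
}

#' Map cerebellar output onto CPG parameters
#'
#' In the full model the 24 outputs are additive corrections: each output
#' (bounded in (-1, 1)) is scaled by half the width of its parameter's
#' clamp interval and added to the basal-ganglia-decoded value before
#' clamping. In cerebellum-only mode the outputs are mapped affinely onto
#' the clamp intervals; in the direct-joint-angle variant the first four
#' outputs are scaled by the motor amplification and read as angles.
#'
#' @param output Length-24 (or at least 4 for `"angles"`) output vector.
#' @param mode One of `"additive"`, `"affine"`, `"angles"`.
#' @param base 6 x 4 matrix of decoded parameters (additive mode only).
#' @param fixed [cpg_fixed()] (angles mode only).
#' @return A clamped 6 x 4 parameter matrix, or joint angles for
#'   `"angles"`.
#' @export
map_cerebellar_output <- function(output, mode = c("additive", "affine", "angles"),
                                  base = NULL, fixed = cpg_fixed()) {
  mode <- match.arg(mode)
  rg <- cpg_param_ranges()
  half <- rep((rg$upper - rg$lower) / 2, 4L)
  if (mode == "additive") {
    stopifnot(!is.null(base))
    clamp_cpg_params(base + matrix(output * half, 6L, 4L))
  } else if (mode == "affine") {
    lo <- rep(rg$lower, 4L)
    clamp_cpg_params(matrix(lo + (output + 1) / 2 * 2 * half, 6L, 4L))
  } else {
    stats::setNames(fixed$Amp * output[1:4] + fixed$U_ref,
                    c("pitch", "yaw", "roll", "elbow"))
  }
}
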