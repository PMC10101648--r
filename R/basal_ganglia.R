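#' Fixed parameters of the basal-ganglia motor loop
#'
#' Rate-model constants of the premotor-input -> striatum D1 -> SNr ->
#' thalamus -> motor cortex loop and its dopamine cell. The synaptic
#' weights and baselines of the loop populations are the published values;
#' the learning-rule constants (`K_b`, `K_d`, `alpha_j`, `tau_w`,
#' `tau_DA`), the Gaussian goal-tuning width `sigma_g`, the noise amplitude
#' and the motor-cortex baseline `B_cortex` are calibrated (no published
#' value) and are marked as such in serialized configurations.
#'
#' `B_cortex` sits just below the tonic thalamic drive (0.9 - 0.6 * 1.1 =
#' 0.24), so the resting motor cortex is silent and the 0.05
#' action-selection threshold has a sub-threshold branch: an untrained
#' network selects actions at random, which is what drives the act-and-
#' sense exploration.
#'
#' @param tau Membrane time constant, ms.
#' @param w_str_snr,w_snr_thal,w_thal_ctx,w_ctx_str Loop weights.
#' @param B_striatum,B_snr,B_thalamus,B_DA Population baselines.
#' @param B_cortex Motor-cortex baseline (calibrated).
#' @param gamma_pre,gamma_post Correlation thresholds of the Hebbian term.
#' @param n_actions Number of concrete-action channels.
#' @param K_b,K_d Slopes of the dopamine modulation for positive / negative
#'   phasic dopamine (calibrated).
#' @param alpha_j Weight-normalization rate (calibrated).
#' @param tau_w,tau_DA Plasticity and dopamine-cell time constants, ms
#'   (calibrated).
#' @param noise_amplitude Half-width of the uniform membrane noise.
#' @param sigma_g Width of the Gaussian tuning used when a sensed
#'   *outcome* is encoded for learning, workspace units (calibrated).
#' @param sigma_g_select Wider tuning used when a desired *goal* is
#'   presented for action selection (calibrated): goals typically lie
#'   between stored outcomes, and the broader activation lets the learned
#'   outcome-action map generalize to them while outcome binding stays
#'   sharp.
#' @param selection_threshold Motor-cortex rate below which a random action
#'   is selected.
#' @param n_premotor Number of premotor input cells.
#' @param n_cells_per_param Population size per CPG parameter.
#' @param weight_sharpness Exponent applied to the raw uniform
#'   action-to-parameter weights (calibrated; larger = more diverse
#'   decoded actions).
#' @param dt Integration step, ms.
#' @return A list of class `bg_params`.
#' @export
bg_params <- function(tau = 10, w_str_snr = 0.8, w_snr_thal = 0.6,
                      w_thal_ctx = 1.0, w_ctx_str = 0.5,
                      B_striatum = 0, B_snr = 1.1, B_thalamus = 0.9,
                      B_DA = 0.1, B_cortex = -0.26,
                      gamma_pre = 0, gamma_post = 0.1,
                      n_actions = 120, K_b = 10, K_d = 5, alpha_j = 0.1,
                      tau_w = 100, tau_DA = 10, noise_amplitude = 0.01,
                      sigma_g = 0.10, sigma_g_select = 0.20,
                      selection_threshold = 0.05,
                      n_premotor = 200, n_cells_per_param = 21,
                      weight_sharpness = 8, dt = 1) {
  structure(as.list(environment()), class = "bg_params")
}

#' Build the fixed random action library
#'
#' Each concrete action is a motor-cortex channel with fixed random
#' weights to 24 value-tuned parameter populations (six CPG parameters per
#' joint, `n_cells_per_param` cells each, preferred values tiling the clamp
#' interval uniformly). Weights are drawn once per run from Uniform(0, 1)
#' raised to `weight_sharpness` and row-normalized: the sharpening makes a
#' few cells dominate each population so that the population-vector
#' readout of different actions spreads across the whole clamp interval
#' (with near-uniform weights every action would decode to the interval
#' midpoint and all concrete actions would produce the same movement).
#' Uses the current RNG state.
#'
#' @param params [bg_params()].
#' @return A list of class `action_library` with the weight matrix `WLIB`
#'   (`n_actions` x `24 * n_cells_per_param`), the preferred values, and
#'   the per-parameter cell index.
#' @export
action_library <- function(params = bg_params()) {
  rg <- cpg_param_ranges()
  nc <- params$n_cells_per_param
  pref_one <- Map(function(lo, hi) seq(lo, hi, length.out = nc), rg$lower, rg$upper)
  # 24 populations: parameter index varies fastest within a joint (column-major 6 x 4)
  pref <- unlist(rep(pref_one, 4L), use.names = FALSE)
  pop <- rep(seq_len(24L), each = nc)
  W <- matrix(stats::runif(params$n_actions * length(pref))^params$weight_sharpness,
              params$n_actions, length(pref))
  W <- W / rowSums(W) * 24  # each action distributes unit weight per population
  structure(list(WLIB = W, preferred = pref, population = pop,
                 n_cells_per_param = nc),
            class = "action_library")
}

#' Build a fresh basal-ganglia network
#'
#' Premotor input cells get preferred 3-D positions by forward kinematics
#' of random joint configurations (uniform in each joint over plus/minus
#' pi), guaranteeing that tuning covers the reachable workspace. Plastic
#' weights start at zero. Uses the current RNG state.
#'
#' @param params [bg_params()].
#' @param lib An [action_library()]; built here if `NULL`.
#' @return A list of class `bg_network`.
#' @export
bg_network <- function(params = bg_params(), lib = NULL) {
  if (is.null(lib)) lib <- action_library(params)
  pos <- t(vapply(seq_len(params$n_premotor),
                  function(i) fk_one(stats::runif(4L, -pi, pi)),
                  numeric(3L)))
  n <- params$n_actions
  state <- list(mp_pre = numeric(params$n_premotor), mp_str = numeric(n),
                mp_snr = numeric(n), mp_thal = numeric(n), mp_ctx = numeric(n),
                mp_par = numeric(ncol(lib$WLIB)), da = params$B_DA)
  structure(list(params = params, lib = lib, premotor_positions = pos,
                 state = state,
                 W = matrix(0, params$n_premotor, n),
                 WDA = numeric(n),
                 last_peak_da = NA_real_),
            class = "bg_network")
}

#' Gaussian goal encoding of the premotor input population
#'
#' Baseline of each premotor input cell for a position:
#' `exp(-||p_i - pos||^2 / (2 sigma^2))`. Desired goals are encoded with
#' the broad selection width, sensed outcomes (for learning) with the
#' sharp binding width.
#'
#' @param goal Numeric length-3 position.
#' @param net [bg_network()].
#' @param sigma Tuning width; defaults to the selection width.
#' @return Numeric baseline vector (one entry per premotor cell).
#' @export
encode_goal <- function(goal, net, sigma = net$params$sigma_g_select) {
  stopifnot(length(goal) == 3L, all(is.finite(goal)))
  d2 <- colSums((t(net$premotor_positions) - as.numeric(goal))^2)
  exp(-d2 / (2 * sigma^2))
}

bg_par_list <- function(p) {
  list(tau = p$tau, dt = p$dt, tau_da = p$tau_DA, tau_w = p$tau_w,
       w_str_snr = p$w_str_snr, w_snr_thal = p$w_snr_thal,
       w_thal_ctx = p$w_thal_ctx, w_ctx_str = p$w_ctx_str,
       B_striatum = p$B_striatum, B_snr = p$B_snr, B_thalamus = p$B_thalamus,
       B_cortex = p$B_cortex, B_DA = p$B_DA, K_b = p$K_b, K_d = p$K_d,
       alpha_j = p$alpha_j, gamma_pre = p$gamma_pre, gamma_post = p$gamma_post,
       noise_amplitude = p$noise_amplitude)
}

#' Advance the basal-ganglia loop
#'
#' Euler-integrates all population membrane potentials (firing rate =
#' positive part) for `n_ms` milliseconds, with optional channel clamping,
#' movement gate `P` for the dopamine cell, and plasticity.
#'
#' @param net [bg_network()].
#' @param baseline Premotor baseline vector (e.g. from [encode_goal()]),
#'   or `NULL` for no input.
#' @param n_ms Simulated time, ms.
#' @param clamp 1-based motor-cortex channel forced to rate 1, or `NA`.
#' @param P Movement gate of the dopamine cell (0 or 1).
#' @param learn Apply the dopamine-modulated Hebbian updates each step.
#' @return Updated network; `net$last_peak_da` holds the peak dopamine
#'   level reached during the call.
#' @export
bg_run <- function(net, baseline = NULL, n_ms = 100, clamp = NA, P = 0,
                   learn = FALSE) {
  if (is.null(baseline)) baseline <- numeric(net$params$n_premotor)
  res <- cpp_bg_run(net$state, list(W = net$W, WDA = net$WDA, WLIB = net$lib$WLIB),
                    baseline, if (is.na(clamp)) -1L else clamp - 1L,
                    as.integer(round(n_ms / net$params$dt)), P, learn,
                    bg_par_list(net$params))
  net$state <- lapply(res$state, as.numeric)
  net$state$da <- res$state$da
  if (learn) {
    net$W <- res$W
    net$WDA <- as.numeric(res$WDA)
  }
  net$last_peak_da <- res$peak_da
  net$last_r_ctx <- as.numeric(res$r_ctx)
  net
}

#' Settle the network to its resting state
#'
#' Simulates with no premotor input long enough for all populations to
#' return to baseline (the tonic SNr-inhibited rest state).
#'
#' @inheritParams bg_run
#' @export
bg_settle <- function(net, n_ms = 200) {
  bg_run(net, baseline = NULL, n_ms = n_ms)
}

#' Select a concrete action for a goal
#'
#' Presents the goal for 200 ms; if the maximum motor-cortex rate stays
#' below the selection threshold (or `force_random`), a uniformly random
#' channel is clamped to rate 1, otherwise the most active channel is.
#' A further 150 ms lets the parameter populations stabilize.
#'
#' @param net [bg_network()] (settled).
#' @param goal Numeric length-3 goal position.
#' @param force_random Always take the random branch.
#' @return List with the updated `net`, the selected `action` index,
#'   `random` (logical branch taken) and `max_ctx` (pre-clamp peak rate).
#' @export
select_action <- function(net, goal, force_random = FALSE) {
  b <- encode_goal(goal, net)
  net <- bg_run(net, b, n_ms = 200)
  mx <- max(net$last_r_ctx)
  random <- force_random || mx < net$params$selection_threshold
  idx <- if (random) sample.int(net$params$n_actions, 1L) else which.max(net$last_r_ctx)
  net <- bg_run(net, b, n_ms = 150, clamp = idx)
  list(net = net, action = idx, random = random, max_ctx = mx)
}

#' Decode CPG parameters from the parameter populations
#'
#' Population-vector readout: for each of the 24 parameter populations the
#' activity-weighted mean of the cells' preferred values, clamped to the
#' admissible interval. A silent population decodes to the interval
#' midpoint (with a warning).
#'
#' @param net [bg_network()] with stabilized parameter populations.
#' @return 6 x 4 matrix of clamped CPG parameters.
#' @export
decode_parameters <- function(net) {
  lib <- net$lib
  r <- pmax(net$state$mp_par, 0)
  rg <- cpg_param_ranges()
  mid <- rep((rg$lower + rg$upper) / 2, 4L)
  n_silent <- 0L
  vals <- vapply(seq_len(24L), function(k) {
    sel <- lib$population == k
    tot <- sum(r[sel])
    if (tot <= 0) {
      n_silent <<- n_silent + 1L
      return(mid[[k]])
    }
    sum(r[sel] * lib$preferred[sel]) / tot
  }, numeric(1L))
  if (n_silent > 0L) {
    warning(n_silent, " silent parameter population(s); decoding to the ",
            "interval midpoint", call. = FALSE)
  }
  clamp_cpg_params(matrix(vals, 6L, 4L))
}

#' Act-and-sense learning step
#'
#' After a movement, the achieved outcome (not the goal) is encoded in the
#' premotor input; the network senses it for 100 ms, then the dopamine
#' gate opens (`P = 1`) for a final 100 ms during which the three-factor
#' Hebbian updates run. The phasic dopamine amplitude reflects the novelty
#' of the outcome: striatal inhibition of the dopamine cell grows with each
#' repetition, so familiar outcomes evoke smaller bursts and less learning.
#'
#' @param net [bg_network()] with the executed action still clamped.
#' @param outcome Achieved hand position (length 3).
#' @param action The executed action channel (kept clamped).
#' @return Updated network; `net$last_peak_da` is the phasic peak.
#' @export
learn_trial <- function(net, outcome, action) {
  b <- encode_goal(outcome, net, sigma = net$params$sigma_g)
  net <- bg_run(net, b, n_ms = 100, clamp = action)
  net <- bg_run(net, b, n_ms = 100, clamp = action, P = 1, learn = TRUE)
  net
}

#' Single Euler step of an isolated rate neuron
#'
#' Reference implementation of the rate equation for one neuron:
#' `tau dmp/dt + mp = excitation - inhibition + B + noise`, rate =
#' positive part. Exposed for fixed-point verification.
#'
#' @param mp Membrane potential.
#' @param excitation,inhibition Summed weighted input rates.
#' @param B Baseline.
#' @param tau Time constant, ms.
#' @param dt Step, ms.
#' @param noise Noise term (default 0).
#' @return List with updated `mp` and `rate`.
#' @export
rate_step <- function(mp, excitation = 0, inhibition = 0, B = 0, tau = 10,
                      dt = 1, noise = 0) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  mp <- mp + dt / tau * (-mp + excitation - inhibition + B + noise)
  list(mp = mp, rate = max(mp, 0))
}

#' Corticostriatal weight update (reference implementation)
#'
#' One step of the three-factor rule: a dopamine-modulated Hebbian term
#' (the positive-clipped correlation between premotor and striatal rates,
#' scaled by the phasic dopamine deviation through slopes `K_b`/`K_d`)
#' minus an activity-dependent normalization; weights floored at zero.
#'
#' @param W Weight matrix (pre x post).
#' @param r_pre,r_post Rate vectors.
#' @param da Current dopamine level.
#' @param params [bg_params()].
#' @return Updated weight matrix.
#' @export
corticostriatal_update <- function(W, r_pre, r_post, da, params = bg_params()) {
  x <- da - params$B_DA
  fda <- if (x > 0) params$K_b * x else params$K_d * x
  C <- pmax(outer(r_pre - mean(r_pre) - params$gamma_pre,
                  r_post - mean(r_post) - params$gamma_post), 0)
  norm <- matrix(params$alpha_j * (r_post - mean(r_post))^2,
                 nrow(W), ncol(W), byrow = TRUE)
  pmax(W + params$dt / params$tau_w * (fda * C - norm), 0)
}

#' Striatum-to-dopamine weight update (reference implementation)
#'
#' Inhibitory prediction weights grow for above-average striatal cells
#' during positive phasic dopamine, so repeated outcomes yield shrinking
#' bursts -- the novelty signal.
#'
#' @param WDA Weight vector (one per striatal cell).
#' @param r_str Striatal rates.
#' @param r_pre_mean Mean premotor rate (the threshold).
#' @param da Current dopamine level.
#' @param params [bg_params()].
#' @return Updated weight vector.
#' @export
da_weight_update <- function(WDA, r_str, r_pre_mean, da, params = bg_params()) {
  x <- da - params$B_DA
  pmax(WDA + params$dt / params$tau_w * (3 * x * pmax(r_str - r_pre_mean, 0)), 0)
}

#' Dopamine-cell step (reference implementation)
#'
#' Relaxation of the dopamine level toward
#' `P * max(0, 1 - sum(WDA * r_str)) + B_DA`.
#'
#' @param da Current dopamine level.
#' @param P Movement gate (0 or 1).
#' @param WDA,r_str Striatal prediction weights and rates.
#' @param params [bg_params()].
#' @return Updated dopamine level.
#' @export
dopamine_step <- function(da, P, WDA, r_str, params = bg_params()) {
  target <- P * max(0, 1 - sum(WDA * r_str)) + params$B_DA
  da + params$dt / params$tau_DA * (-da + target)
}
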