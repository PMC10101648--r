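#' Fixed CPG parameters
#'
#' The non-adapted constants of each central pattern generator: the width
#' `A_f` of the N-shaped fast current, the slow time constant expressed as a
#' multiple of the membrane time constant (`tau_s = tau_s_factor * tau_m`),
#' the descending gain and offset of the pattern-formation sigmoid, the
#' rhythm-generator-to-pattern-formation and pattern-formation-to-motor-
#' neuron weights, the motor amplification `Amp`, the slow-current reversal
#' potential `E_s` and the per-joint reference angles `U_ref`.
#'
#' `E_s` and the rhythm-generator initial conditions have no published
#' value; the defaults (`E_s = 0`, symmetry-broken `V_e = 0.1`,
#' `V_f = -0.1`) give a clean all-zero fixed point when no current is
#' injected and guarantee that the extensor and flexor chains do not stay
#' identical forever. All values are configurable.
#'
#' @param A_f Width of the N-shaped fast current.
#' @param tau_s_factor Slow time constant as a multiple of `tau_m`.
#' @param alpha_PF,theta_PF Descending gain and offset of the
#'   pattern-formation sigmoid.
#' @param W_rg,W_pf Fixed feed-forward weights.
#' @param Amp Motor-neuron amplification (bounds the joint excursion to
#'   `U_ref` plus or minus `Amp` radians).
#' @param E_s Slow-current reversal potential.
#' @param U_ref Reference joint angles (radians, length 4).
#' @param v_init_e,v_init_f Initial membrane potentials of the extensor and
#'   flexor rhythm-generator cells.
#' @param guard Integration guard: an error is raised if |V| exceeds it.
#' @return A list of class `cpg_fixed`.
#' @export
cpg_fixed <- function(A_f = 5, tau_s_factor = 20, alpha_PF = 1, theta_PF = 0,
                      W_rg = 1, W_pf = 1, Amp = 5, E_s = 0,
                      U_ref = c(0, 0, 0, 0),
                      v_init_e = 0.1, v_init_f = -0.1, guard = 1e6) {
  stopifnot(length(U_ref) == 4L)
  structure(list(A_f = A_f, tau_s_factor = tau_s_factor, alpha_PF = alpha_PF,
                 theta_PF = theta_PF, W_rg = W_rg, W_pf = W_pf, Amp = Amp,
                 E_s = E_s, U_ref = U_ref, v_init_e = v_init_e,
                 v_init_f = v_init_f, guard = guard),
            class = "cpg_fixed")
}

#' Clamp intervals of the six tunable CPG parameters
#'
#' @return A tibble with columns `param`, `lower`, `upper` in the canonical
#'   order `tau_m`, `sigma_f`, `sigma_s`, `i_inj`, `alpha_0`, `theta_0`.
#' @export
cpg_param_ranges <- function() {
  tibble::tibble(
    param = c("tau_m", "sigma_f", "sigma_s", "i_inj", "alpha_0", "theta_0"),
    lower = c(5, 5, 5, -4, 0.001, 0.001),
    upper = c(15, 10, 10, 4, 2, 2))
}

#' Project raw parameter values onto their admissible intervals
#'
#' @param raw Numeric vector of length 6 (one joint, canonical order), a
#'   6 x 4 matrix (all joints) or a length-24 vector (column-major, six
#'   parameters per joint).
#' @return Clamped values, same shape as the input.
#' @export
clamp_cpg_params <- function(raw) {
  rg <- cpg_param_ranges()
  if (is.matrix(raw)) {
    stopifnot(nrow(raw) == 6L)
    return(apply(raw, 2L, function(col) pmin(pmax(col, rg$lower), rg$upper)))
  }
  if (length(raw) == 24L) {
    m <- matrix(raw, 6L, 4L)
    return(as.numeric(clamp_cpg_params(m)))
  }
  stopifnot(length(raw) == 6L, all(is.finite(raw)))
  stats::setNames(pmin(pmax(raw, rg$lower), rg$upper), rg$param)
}

#' One Euler step of the rhythm-generator cells
#'
#' Advances the membrane potentials `V_e`, `V_f` and the lumped slow
#' currents `q_e`, `q_f` of the extensor and flexor rhythm-generator cells
#' by `dt` milliseconds. The two cells form a reciprocal half-centre: the
#' injected current drives the extensor cell with positive and the flexor
#' cell with negative sign, so `i_inj` grades the extensor-flexor balance
#' (and thereby the joint excursion) smoothly.
#'
#' @param state List with `V_e`, `q_e`, `V_f`, `q_f`.
#' @param params Named numeric of the six tunable parameters (only
#'   `tau_m`, `sigma_f`, `sigma_s`, `i_inj` are used here).
#' @param fixed [cpg_fixed()] parameters.
#' @param dt Step, ms (> 0).
#' @return Updated state list.
#' @export
rg_step <- function(state, params, fixed = cpg_fixed(), dt = 1) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  tau_m <- params[["tau_m"]]; tau_s <- fixed$tau_s_factor * tau_m
  drv <- function(V, q, drive) {
    dV <- -(V - fixed$A_f * tanh((params[["sigma_f"]] / fixed$A_f) * V) +
              q - drive) / tau_m
    dq <- (-q + params[["sigma_s"]] * (V - fixed$E_s)) / tau_s
    c(dV, dq)
  }
  # reciprocal half-center drive: the flexor cell receives -i_inj
  de <- drv(state$V_e, state$q_e, params[["i_inj"]])
  df <- drv(state$V_f, state$q_f, -params[["i_inj"]])
  list(V_e = state$V_e + dt * de[1L], q_e = state$q_e + dt * de[2L],
       V_f = state$V_f + dt * df[1L], q_f = state$q_f + dt * df[2L])
}

#' Pattern-formation activation
#'
#' Logistic activation of a pattern-formation cell from its
#' rhythm-generator input and optional sensory inputs. The input is the
#' weighted sum normalized by `n + 1` where `n` is the number of sensory
#' afferents (the model is run open loop, so sensory weights default to
#' none).
#'
#' @param rg_input Activation of the rhythm-generator cell.
#' @param params Tunable parameters (uses `alpha_0`, `theta_0`).
#' @param fixed [cpg_fixed()] parameters.
#' @param sensory,sensory_weights Optional sensory activations and weights.
#' @return Activation in (0, 1).
#' @export
pf_activation <- function(rg_input, params, fixed = cpg_fixed(),
                          sensory = numeric(), sensory_weights = numeric()) {
  stopifnot(length(sensory) == length(sensory_weights))
  I_PF <- (fixed$W_rg * rg_input + sum(sensory_weights * sensory)) /
    (length(sensory) + 1)
  1 / (1 + exp(params[["alpha_0"]] * fixed$alpha_PF *
                 ((params[["theta_0"]] + fixed$theta_PF) - I_PF)))
}

#' Motor-neuron activation
#'
#' Fixed-slope logistic (slope 5, centre 0.5) of the normalized
#' pattern-formation drive plus optional sensory inputs.
#'
#' @inheritParams pf_activation
#' @param pf Pattern-formation activation.
#' @return Activation in (0, 1).
#' @export
mn_activation <- function(pf, fixed = cpg_fixed(),
                          sensory = numeric(), sensory_weights = numeric()) {
  stopifnot(length(sensory) == length(sensory_weights))
  I_MN <- (fixed$W_pf * pf + sum(sensory_weights * sensory)) /
    (length(sensory) + 1)
  1 / (1 + exp(5 * (0.5 - I_MN)))
}

#' Joint angle from the two motor neurons
#'
#' `U = Amp * (MN_E - MN_F) + U_ref`: the difference between the extensor
#' and flexor motor-neuron activations, amplified and offset by the joint's
#' reference angle. The excursion is therefore bounded by `Amp`.
#'
#' @param mn_e,mn_f Extensor and flexor motor-neuron activations in (0, 1).
#' @param fixed [cpg_fixed()] parameters.
#' @param joint Joint index 1-4 (selects the `U_ref` entry).
#' @return Joint angle in radians.
#' @export
joint_angle <- function(mn_e, mn_f, fixed = cpg_fixed(), joint = 1L) {
  fixed$Amp * (mn_e - mn_f) + fixed$U_ref[[joint]]
}

#' Execute a movement: CPG parameters to final joint angles
#'
#' Integrates the four per-joint CPG networks (two rhythm-generator cells,
#' mirrored extensor/flexor pattern-formation and motor-neuron chains) from
#' their standard initial state for `duration` ms and reads out each joint
#' angle as the mean of `U` over the final `readout_ms` window. The
#' defaults read the ballistic phase of the movement (the reciprocal-drive
#' excursion before the slow potassium current equilibrates), which spans
#' the arm's workspace; the time average makes the parameter-to-angle map
#' insensitive to the oscillator phase at the readout instant, so nearby
#' parameter sets produce nearby angles -- the property the cerebellum's
#' perturbation learning relies on. The map is deterministic.
#'
#' @param params 6 x 4 matrix (rows in [cpg_param_ranges()] order, one
#'   column per joint) or a length-24 vector; values are clamped first.
#' @param fixed [cpg_fixed()] parameters.
#' @param duration Movement duration, ms.
#' @param dt Euler step, ms.
#' @param readout_ms Width of the terminal averaging window, ms.
#' @return Named numeric of the four joint angles (radians).
#' @export
execute_movement <- function(params, fixed = cpg_fixed(), duration = 200,
                             dt = 1, readout_ms = 100) {
  if (duration <= 0 || dt <= 0) stop("`duration` and `dt` must be positive", call. = FALSE)
  m <- clamp_cpg_params(if (is.matrix(params)) params else matrix(params, 6L, 4L))
  ang <- vapply(seq_len(4L), function(j) {
    fx <- unclass(fixed)
    fx$U_ref_joint <- fixed$U_ref[[j]]
    cpp_cpg_joint(m[, j], fx, duration, dt, readout_ms, FALSE,
                  fixed$v_init_e, fixed$v_init_f, fixed$guard)[[1L]]
  }, numeric(1L))
  stats::setNames(ang, c("pitch", "yaw", "roll", "elbow"))
}

# V trace of the extensor rhythm-generator cell (for oracle tests)
rg_v_trace <- function(params, fixed = cpg_fixed(), duration = 1000, dt = 1,
                       v_init = 0.1) {
  fx <- unclass(fixed)
  fx$U_ref_joint <- fixed$U_ref[[1L]]
  cpp_cpg_joint(params, fx, duration, dt, duration, TRUE, v_init,
                -v_init, fixed$guard)
}
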