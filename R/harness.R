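#' Default run configuration
#'
#' Nested configuration covering every tunable constant of the model.
#' Published constants default to their published values; constants with no
#' published value are listed under each section's `calibrated` vector and
#' flagged as such when the configuration is serialized.
#'
#' @param ... Named overrides, e.g. `bg = list(n_actions = 30)`.
#' @return A list of class `motorloop_config`.
#' @export
motorloop_config <- function(...) {
  cfg <- list(
    cpg = list(A_f = 5, tau_s_factor = 20, alpha_PF = 1, theta_PF = 0,
               W_rg = 1, W_pf = 1, Amp = 5, E_s = 0,
               U_ref = c(0, 0, 0, 0), duration = 200, dt = 1,
               readout_ms = 100,
               calibrated = c("E_s", "duration", "readout_ms")),
    bg = list(tau = 10, w_str_snr = 0.8, w_snr_thal = 0.6, w_thal_ctx = 1.0,
              w_ctx_str = 0.5, B_striatum = 0, B_snr = 1.1, B_thalamus = 0.9,
              B_DA = 0.1, B_cortex = -0.26, gamma_pre = 0, gamma_post = 0.1,
              n_actions = 120, K_b = 10, K_d = 5, alpha_j = 0.1,
              tau_w = 100, tau_DA = 10, noise_amplitude = 0.01,
              sigma_g = 0.10, sigma_g_select = 0.20,
              selection_threshold = 0.05, n_premotor = 200,
              n_cells_per_param = 21, weight_sharpness = 8, dt = 1,
              calibrated = c("B_cortex", "K_b", "K_d", "alpha_j", "tau_w",
                             "tau_DA", "noise_amplitude", "sigma_g", "sigma_g_select",
                             "n_premotor", "n_cells_per_param",
                             "weight_sharpness")),
    cerebellum = list(n_units = 400, n_outputs = 24, tau = 10, f = 9, A = 20,
                      eta = 0.8, input_weight_range = 0.2,
                      init_weight_sd = 0.05, x_init_range = 0.01,
                      xbar_tau = 5, ebar_coef = 0.2, weight_cap = 1,
                      delta_max = 1e-3, dt = 1, input_ms = 200, free_ms = 200,
                      output_gain = 0.25,
                      calibrated = c("tau", "xbar_tau", "ebar_coef",
                                     "weight_cap", "delta_max",
                                     "output_gain")),
    goals = list(min_dist = 0.5, max_tries = 10000, competence_deg = 12,
                 calibrated = c("competence_deg")),
    schedule = list(baseline_trials = 100, perturbed_trials = 200,
                    instruction_delay = 2, strategy_off_to_rotation_off = 10,
                    rotation_deg = 45, washout_trials = 90,
                    calibrated = character()))
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec, call. = FALSE)
    for (key in names(over[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, "$", key, call. = FALSE)
      cfg[[sec]][[key]] <- over[[sec]][[key]]
    }
  }
  validate_config(structure(cfg, class = "motorloop_config"))
}

validate_config <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!ok) stop("config validation: `", key, "` ", msg, call. = FALSE)
  }
  rg <- cpg_param_ranges()
  chk(cfg$cpg$dt > 0, "cpg$dt", "must be positive")
  chk(cfg$cpg$duration >= cfg$cpg$readout_ms, "cpg$duration",
      "must be at least the readout window")
  chk(cfg$bg$n_actions >= 1, "bg$n_actions", "must be at least 1")
  chk(cfg$bg$selection_threshold > 0, "bg$selection_threshold", "must be positive")
  chk(cfg$cerebellum$f >= 0, "cerebellum$f", "must be non-negative")
  chk(cfg$cerebellum$A >= 0, "cerebellum$A", "must be non-negative")
  chk(cfg$cerebellum$eta >= 0, "cerebellum$eta", "must be non-negative")
  chk(cfg$cerebellum$n_outputs <= cfg$cerebellum$n_units, "cerebellum$n_outputs",
      "cannot exceed the number of reservoir units")
  chk(cfg$goals$min_dist >= 0, "goals$min_dist", "must be non-negative")
  chk(all(unlist(cfg$schedule[c("baseline_trials", "perturbed_trials",
                                "instruction_delay",
                                "strategy_off_to_rotation_off",
                                "washout_trials")]) >= 0),
      "schedule", "trial counts must be non-negative")
  cfg
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML; unspecified keys take their
#' defaults, unknown keys and out-of-range values raise a validation error
#' naming the key. `save_config()` / `load_config()` round-trip exactly.
#'
#' @param path File path.
#' @return `load_config()` returns a validated [motorloop_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw <- lapply(raw, function(sec) sec[names(sec) != "calibrated"])
  do.call(motorloop_config, raw)
}

#' @rdname load_config
#' @param config A [motorloop_config()].
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a resolved configuration
#'
#' Stable fingerprint used in run summaries so that logged results can be
#' matched to the exact configuration that produced them.
#'
#' @param config A [motorloop_config()].
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

## -- named RNG streams ------------------------------------------------------
## One independent stream per stochastic component, so that ablating one
## component (e.g. the cerebellum) leaves every other component's draws
## unchanged -- required for seed-sharing ablation comparisons.

make_streams <- function(seed, names = c("goals", "library", "bg", "cerebellum")) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(names))
  streams <- stats::setNames(vector("list", length(names)), names)
  for (i in seq_along(names)) {
    set.seed(seeds[[i]])
    streams[[i]] <- get_rng_state()
  }
  streams
}

get_rng_state <- function() {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  get(".Random.seed", envir = globalenv())
}

set_rng_state <- function(state) {
  assign(".Random.seed", state, envir = globalenv())
}

# Evaluate fn() with the named stream active; returns list(value, streams).
with_stream <- function(streams, name, fn) {
  old <- get_rng_state()
  set_rng_state(streams[[name]])
  value <- fn()
  streams[[name]] <- get_rng_state()
  set_rng_state(old)
  list(value = value, streams = streams)
}

#' Build a fully wired model
#'
#' Assembles the basal-ganglia network (with its action library), the
#' cerebellar reservoir and the CPG constants under a single seed that
#' fans out into independent named streams (goal sampling, action library,
#' loop noise, reservoir). Three presets are provided: `unit` (5 actions,
#' 50 reservoir units, 20 premotor cells -- smoke tests), `reduced` (30
#' actions, full 400-unit reservoir, shortened schedules -- desk-scale
#' runs) and `full` (120 actions, the published population sizes).
#'
#' @param preset One of `"unit"`, `"reduced"`, `"full"`.
#' @param seed Integer seed for all randomness in the model's lifetime.
#' @param n_goal_inputs Number of cerebellar goal-input cells.
#' @param config Optional [motorloop_config()] overriding the preset.
#' @return A list of class `motor_model`.
#' @export
motor_model <- function(preset = c("reduced", "unit", "full"), seed = 1,
                        n_goal_inputs = 8, config = NULL) {
  preset <- match.arg(preset)
  if (is.null(config)) {
    config <- switch(preset,
      unit = motorloop_config(bg = list(n_actions = 5, n_premotor = 20,
                                        n_cells_per_param = 11),
                              cerebellum = list(n_units = 50)),
      reduced = motorloop_config(bg = list(n_actions = 30),
                                 schedule = list(baseline_trials = 30,
                                                 perturbed_trials = 60,
                                                 washout_trials = 30)),
      full = motorloop_config())
  }
  streams <- make_streams(seed)
  bgp <- do.call(bg_params, config$bg[setdiff(names(config$bg), "calibrated")])
  res <- with_stream(streams, "library", function() {
    lib <- action_library(bgp)
    bg_network(bgp, lib)
  })
  streams <- res$streams
  net <- res$value
  cp <- config$cerebellum
  rp <- do.call(reservoir_params, cp[setdiff(names(cp), "calibrated")])
  res2 <- with_stream(streams, "cerebellum", function() reservoir(rp, n_goal_inputs))
  streams <- res2$streams
  fx_keys <- c("A_f", "tau_s_factor", "alpha_PF", "theta_PF", "W_rg", "W_pf",
               "Amp", "E_s", "U_ref")
  structure(list(preset = preset, seed = seed, config = config,
                 streams = streams, bg = net, cerebellum = res2$value,
                 cpg_fixed = do.call(cpg_fixed, config$cpg[fx_keys]),
                 pretrained = FALSE, pretraining = NULL,
                 cached_params = NULL),
            class = "motor_model")
}

#' @rdname motor_model
#' @export
make_fixture <- function(preset = c("reduced", "unit", "full"), seed = 1, ...) {
  motor_model(preset = preset, seed = seed, ...)
}

#' @export
print.motor_model <- function(x, ...) {
  cat("<motor_model> preset:", x$preset, " seed:", x$seed, "\n")
  cat("  actions:", x$bg$params$n_actions,
      " premotor cells:", x$bg$params$n_premotor,
      " reservoir units:", x$cerebellum$params$n_units, "\n")
  cat("  pretrained:", x$pretrained, "\n")
  invisible(x)
}

# movement execution shared by all experiment drivers
model_execute <- function(model, params) {
  cfg <- model$config$cpg
  ang <- execute_movement(params, model$cpg_fixed, duration = cfg$duration,
                          dt = cfg$dt, readout_ms = cfg$readout_ms)
  list(angles = ang, position = fk_one(ang))
}

#' Summary of a model run for serialization
#'
#' @param model A [motor_model()].
#' @param extra Named list merged into the summary.
#' @return A list that serializes to JSON and reloads losslessly.
#' @export
run_summary <- function(model, extra = list()) {
  c(list(preset = model$preset, seed = model$seed,
         config_hash = config_hash(model$config),
         n_actions = model$bg$params$n_actions,
         n_premotor = model$bg$params$n_premotor,
         n_reservoir_units = model$cerebellum$params$n_units,
         pretrained = model$pretrained),
    extra)
}
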