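#' Tidy a reaching run
#'
#' @param x A `reaching_run`.
#' @param ... Unused.
#' @return The per-trial tibble.
#' @method tidy reaching_run
#' @export
tidy.reaching_run <- function(x, ...) x$trials

#' @rdname tidy.reaching_run
#' @method tidy adaptation_run
#' @export
tidy.adaptation_run <- function(x, ...) x$trials

#' One-row summary of a reaching run
#'
#' Reports the mean error over the first and last windows, the minimum of
#' the moving-average error and where it occurred -- the quantities used to
#' judge learning and late-training instability.
#'
#' @param x A `reaching_run`.
#' @param window Averaging window, trials.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance reaching_run
#' @export
glance.reaching_run <- function(x, window = 50, ...) {
  e <- x$trials$error
  n <- length(e)
  w <- min(window, n)
  ma <- stats::filter(e, rep(1 / w, w), sides = 1)
  tibble::tibble(
    n_trials = n, n_goals = nrow(x$goals), mode = x$mode,
    first_window_error = mean(e[seq_len(w)]),
    final_window_error = mean(e[seq(n - w + 1L, n)]),
    min_window_error = min(ma, na.rm = TRUE),
    min_window_trial = which.min(ma))
}

#' One-row summary of an adaptation run
#'
#' Per-phase mean absolute angular errors plus the first perturbed-trial
#' error and the first washout-trial (aftereffect) error, both signed.
#'
#' @param x An `adaptation_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance adaptation_run
#' @export
glance.adaptation_run <- function(x, ...) {
  tr <- x$trials
  ph <- function(p) mean(abs(tr$angular_error[tr$phase == p]))
  pert <- tr[tr$phase == "perturbation", ]
  wash <- tr[tr$phase == "washout", ]
  tibble::tibble(
    condition = x$schedule$condition,
    ablated = x$ablate_cerebellum,
    baseline_error = ph("baseline"),
    perturbation_error = ph("perturbation"),
    washout_error = if (nrow(wash)) ph("washout") else NA_real_,
    first_perturbed_error = pert$angular_error[[1L]],
    last_perturbed_error = pert$angular_error[[nrow(pert)]],
    first_washout_error = if (nrow(wash)) wash$angular_error[[1L]] else NA_real_)
}
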