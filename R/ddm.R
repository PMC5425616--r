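## Drift-diffusion simulators (pDDM and eDDM).

#' Simulate a single pDDM trial
#'
#' Runs the Euler discretization of the Wiener diffusion: starting at the
#' bias, each step adds a Gaussian increment with mean `drift * dt` and
#' standard deviation `sqrt(dt) * diffusion` until the accumulator reaches
#' `+boundary` (choice 1) or `-boundary` (choice 2), or `max_time` elapses.
#' Crossing exactly at a boundary counts as a decision. Uses the current R
#' random number stream; call `set.seed()` for reproducibility.
#'
#' @param params A [pddm_params()] object.
#' @param max_time Maximum accumulation time in seconds (> dt).
#' @return A list with `choice` (1, 2 or NA), `decision_time`
#'   (crossing step * dt + ndt, or NA), `timed_out`, and `trace`, the full
#'   decision-variable path with its crossing step.
#' @export
#' @examples
#' set.seed(1)
#' simulate_pddm_trial(pddm_params(drift = 2, boundary = 1.4), max_time = 5)$choice
simulate_pddm_trial <- function(params, max_time = 5) {
  stopifnot(inherits(params, "pddm_params"))
  if (max_time <= params$dt) stop("max_time must exceed dt", call. = FALSE)
  n_steps <- floor(max_time / params$dt)
  y <- numeric(n_steps + 1)
  y[1] <- params$bias
  crossing <- NA_integer_
  choice <- NA_integer_
  sd_step <- sqrt(params$dt) * params$diffusion
  for (k in seq_len(n_steps)) {
    y[k + 1] <- y[k] + params$drift * params$dt + stats::rnorm(1, 0, sd_step)
    if (abs(y[k + 1]) >= params$boundary) {
      crossing <- k
      choice <- if (y[k + 1] > 0) 1L else 2L
      break
    }
  }
  timed_out <- is.na(crossing)
  trace <- list(decision_variable = y[seq_len(if (timed_out) n_steps + 1
                                              else crossing + 1)],
                crossing_step = crossing)
  list(choice = choice,
       decision_time = if (timed_out) NA_real_
                       else crossing * params$dt + params$ndt,
       timed_out = timed_out,
       trace = trace)
}

#' Simulate many pDDM trials
#'
#' Vectorized batch version of [simulate_pddm_trial()]; all trials share the
#' same parameters and advance step by step together.
#'
#' @inheritParams simulate_pddm_trial
#' @param n_trials Number of trials.
#' @param seed Optional integer seed for reproducibility.
#' @param condition Condition label stored in the result.
#' @return A [response_set()]. `true_choice` is set to 1: positive drift
#'   means alternative 1 is the correct response.
#' @export
simulate_pddm <- function(params, n_trials, max_time = 5, seed = NULL,
                          condition = "pddm") {
  stopifnot(inherits(params, "pddm_params"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- floor(max_time / params$dt)
  walk <- .walk_gaussian(n_trials, start = params$bias,
                         threshold = params$boundary,
                         inc_mean = params$drift * params$dt,
                         inc_sd = sqrt(params$dt) * params$diffusion,
                         n_steps = n_steps)
  .assemble_responses(walk, dt = params$dt, ndt = rep(params$ndt, n_trials),
                      max_rt = max_time, condition = condition,
                      true_choice = 1L)
}

#' Draw one trial's parameters from the eDDM variability distributions
#'
#' Drift is Gaussian, bias and non-decision time are uniform; zero spreads
#' return the means exactly. Non-decision time is truncated at 0.
#'
#' @param ext An [eddm_params()] object.
#' @return A [pddm_params()] object for that trial.
#' @export
sample_eddm_trial_params <- function(ext) {
  stopifnot(inherits(ext, "eddm_params"))
  v <- if (ext$drift_sd == 0) ext$mean_drift
       else stats::rnorm(1, ext$mean_drift, ext$drift_sd)
  z <- if (ext$bias_spread == 0) ext$mean_bias
       else stats::runif(1, ext$mean_bias - ext$bias_spread / 2,
                         ext$mean_bias + ext$bias_spread / 2)
  tnd <- .sample_ndt(1, ext$mean_ndt, ext$ndt_spread)
  pddm_params(drift = v, boundary = ext$boundary, bias = z, ndt = tnd,
              diffusion = ext$diffusion, dt = ext$dt)
}

#' Simulate the extended drift-diffusion model
#'
#' Per trial, drift, bias and non-decision time are drawn from their
#' inter-trial variability distributions, then the diffusion runs as in the
#' pDDM. Trials not crossing by `max_time`, or whose total response time
#' exceeds it, are flagged timed out and carry `max_time` as their RT.
#'
#' @param ext An [eddm_params()] object.
#' @param n_trials Number of trials.
#' @param max_time Timeout in seconds.
#' @param seed Optional integer seed.
#' @param condition Condition label.
#' @return A [response_set()] with `true_choice = 1`.
#' @export
#' @examples
#' e <- eddm_params(mean_drift = 2, drift_sd = 1.5, boundary = 1.4,
#'                  mean_ndt = 0.4, ndt_spread = 0.2)
#' r <- simulate_eddm(e, 1000, seed = 7)
#' mean(r$choice == 1, na.rm = TRUE)
simulate_eddm <- function(ext, n_trials, max_time = 5, seed = NULL,
                          condition = "eddm") {
  stopifnot(inherits(ext, "eddm_params"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- if (ext$drift_sd == 0) rep(ext$mean_drift, n_trials)
       else stats::rnorm(n_trials, ext$mean_drift, ext$drift_sd)
  z <- if (ext$bias_spread == 0) rep(ext$mean_bias, n_trials)
       else stats::runif(n_trials, ext$mean_bias - ext$bias_spread / 2,
                         ext$mean_bias + ext$bias_spread / 2)
  tnd <- .sample_ndt(n_trials, ext$mean_ndt, ext$ndt_spread)
  n_steps <- floor(max_time / ext$dt)
  walk <- .walk_gaussian(n_trials, start = z, threshold = ext$boundary,
                         inc_mean = v * ext$dt,
                         inc_sd = sqrt(ext$dt) * ext$diffusion,
                         n_steps = n_steps)
  .assemble_responses(walk, dt = ext$dt, ndt = tnd, max_rt = max_time,
                      condition = condition, true_choice = 1L)
}
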