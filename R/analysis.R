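## Response-distribution summaries and the two parameter-sweep experiments
## (task difficulty; slow vs fast errors).

.RT_QUANTILES <- c(0.1, 0.3, 0.5, 0.7, 0.9)

#' Summarize a response set
#'
#' Computes accuracy, median RTs and the standard RT quantiles (0.1, 0.3,
#' 0.5, 0.7, 0.9) for correct and error responses. Timed-out trials are
#' excluded from both the accuracy and all RT statistics; quantiles use
#' linear interpolation between order statistics.
#'
#' @param responses A [response_set()] with known `true_choice`.
#' @return A list of class `response_summary`: `n`, `n_decided`,
#'   `proportion_correct`, `median_rt`, `median_rt_correct`,
#'   `median_rt_error`, `rt_quantiles_correct`, `rt_quantiles_error`,
#'   `timeout_fraction`.
#' @export
summarize_responses <- function(responses) {
  stopifnot(inherits(responses, "response_set"))
  dec <- !responses$timed_out
  if (!any(dec)) stop("no decided trials to summarize", call. = FALSE)
  if (all(is.na(responses$true_choice)))
    stop("true_choice is unknown; cannot score correctness", call. = FALSE)
  correct <- responses$choice == responses$true_choice
  rt <- responses$rt
  qc <- if (any(dec & correct)) stats::quantile(rt[dec & correct],
                                                .RT_QUANTILES, names = FALSE)
        else rep(NA_real_, 5)
  qe <- if (any(dec & !correct)) stats::quantile(rt[dec & !correct],
                                                 .RT_QUANTILES,
                                                 names = FALSE)
        else rep(NA_real_, 5)
  structure(list(
    n = nrow(responses),
    n_decided = sum(dec),
    proportion_correct = mean(correct[dec]),
    median_rt = stats::median(rt[dec]),
    median_rt_correct = if (any(dec & correct))
      stats::median(rt[dec & correct]) else NA_real_,
    median_rt_error = if (any(dec & !correct))
      stats::median(rt[dec & !correct]) else NA_real_,
    rt_quantiles_correct = stats::setNames(qc, .RT_QUANTILES),
    rt_quantiles_error = stats::setNames(qe, .RT_QUANTILES),
    timeout_fraction = mean(!dec)), class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("response_summary: %d trials (%.1f%% timed out)\n", x$n,
              100 * x$timeout_fraction))
  cat(sprintf("  proportion correct %.3f | median RT %.0f ms (correct %.0f, error %.0f)\n",
              x$proportion_correct, 1000 * x$median_rt,
              1000 * x$median_rt_correct, 1000 * x$median_rt_error))
  invisible(x)
}

.sweep_fixed_defaults <- function() {
  list(bound = 0.8, mean_prior = 0.5, ndt = 0.4, ndt_spread = 0.2,
       lapse_prob = 0, timeout_lapse_prob = 0, feature_means = c(25, -25),
       dt = 0.05, max_rt = 5)
}

.run_sweep <- function(grid, fixed, n_trials, seed) {
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- ebm_params(bound = fixed$bound, mean_noise = grid$mean_noise[i],
                    noise_var = grid$noise_var[i],
                    mean_prior = fixed$mean_prior,
                    prior_spread = grid$prior_spread[i],
                    ndt = fixed$ndt, ndt_spread = fixed$ndt_spread,
                    lapse_prob = fixed$lapse_prob,
                    timeout_lapse_prob = fixed$timeout_lapse_prob,
                    feature_means = fixed$feature_means,
                    dt = fixed$dt, max_rt = fixed$max_rt)
    cell_seed <- (seed + i) %% .Machine$integer.max
    s <- summarize_responses(simulate_ebm(p, n_trials, seed = cell_seed))
    rows[[i]] <- data.frame(
      mean_noise = grid$mean_noise[i], noise_var = grid$noise_var[i],
      prior_spread = grid$prior_spread[i],
      proportion_correct = s$proportion_correct,
      median_rt = s$median_rt,
      median_rt_correct = s$median_rt_correct,
      median_rt_error = s$median_rt_error,
      rt_diff = s$median_rt_correct - s$median_rt_error,
      timeout_fraction = s$timeout_fraction,
      n_trials = n_trials, seed = cell_seed)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Task-difficulty parameter sweep
#'
#' Simulates the eBM over a grid of mean noise level (log-spaced over
#' `sigma_range`) and noise variability (log-spaced over `eta_range`), with
#' the reference protocol's fixed parameters (bound 0.8, mean prior 0.5, prior
#' spread 0.2, non-decision time 0.4 s with spread 0.2 s, no lapses, feature
#' means +/-25, dt 0.05 s, 5 s timeout), and records per-cell accuracy and
#' median RT. Difficulty in the eBM is carried by the mean noise level, the
#' analogue of (inverse) mean drift in the eDDM.
#'
#' @param sigma_range Range of the mean noise level (default `c(25, 2500)`).
#' @param eta_range Range of the noise variability (default
#'   `c(1e-4, 0.01)`).
#' @param n_grid Grid dimensions `c(n_sigma, n_eta)` (default 20 x 20).
#' @param n_trials Trials per grid cell (the reference protocol used 100,000;
#'   10,000 keeps the sweep in the minutes range).
#' @param seed Integer seed; each cell derives its own seed from it.
#' @param fixed Optional overrides of the fixed sweep parameters.
#' @return A `sweep_result` data frame, one row per cell, with columns
#'   `mean_noise`, `noise_var`, `prior_spread`, `proportion_correct`,
#'   `median_rt`, `median_rt_correct`, `median_rt_error`, `rt_diff`,
#'   `timeout_fraction`, `n_trials`, `seed`.
#' @export
sweep_task_difficulty <- function(sigma_range = c(25, 2500),
                                  eta_range = c(1e-4, 0.01),
                                  n_grid = c(20, 20), n_trials = 10000,
                                  seed = 1, fixed = list()) {
  fx <- utils::modifyList(.sweep_fixed_defaults(), fixed)
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_grid[1]))
  etas <- exp(seq(log(eta_range[1]), log(eta_range[2]),
                  length.out = n_grid[2]))
  grid <- expand.grid(mean_noise = sigmas, noise_var = etas)
  grid$prior_spread <- 0.2
  .run_sweep(grid, fx, n_trials, seed)
}

#' Slow/fast-error parameter sweep
#'
#' Simulates the eBM over a grid of noise variability (log-spaced) and prior
#' spread (linear), at fixed mean noise level 222.5538 and the sweep
#' protocol's remaining fixed parameters, and records the median RT
#' difference between correct and error responses per cell. Large noise
#' variability produces slow errors (negative difference), large prior
#' spread with small noise variability produces fast errors (positive
#' difference).
#'
#' @param eta_range Range of the noise variability (log-spaced grid).
#' @param sp_range Range of the prior spread (linear grid; upper end 0.3584
#'   keeps sampled priors below the bound 0.8).
#' @param n_grid Grid dimensions `c(n_eta, n_sp)`.
#' @param n_trials Trials per cell.
#' @param seed Integer seed.
#' @param mean_noise Fixed mean noise level.
#' @param fixed Optional overrides of the fixed sweep parameters.
#' @return A `sweep_result` data frame as in [sweep_task_difficulty()].
#' @export
sweep_error_speed <- function(eta_range = c(1e-4, 0.01),
                              sp_range = c(0, 0.3584), n_grid = c(20, 20),
                              n_trials = 10000, seed = 1,
                              mean_noise = 222.5538, fixed = list()) {
  fx <- utils::modifyList(.sweep_fixed_defaults(), fixed)
  etas <- exp(seq(log(eta_range[1]), log(eta_range[2]),
                  length.out = n_grid[1]))
  sps <- seq(sp_range[1], sp_range[2], length.out = n_grid[2])
  grid <- expand.grid(noise_var = etas, prior_spread = sps)
  grid$mean_noise <- mean_noise
  .run_sweep(grid, fx, n_trials, seed)
}

#' Quantile-probability plot data
#'
#' Arranges per-condition summaries into the quantile-probability format:
#' for each condition, the five RT quantiles of correct responses are paired
#' with the correct-response probability and the error quantiles with the
#' error probability, so that plotting `rt` against `response_prob` gives
#' the familiar fan shape across difficulty levels.
#'
#' @param summaries A list of `response_summary` objects.
#' @param labels Optional condition labels.
#' @return A data frame with columns `condition`, `type`
#'   (correct/error), `response_prob`, `quantile`, `rt`.
#' @export
quantile_probability_data <- function(summaries, labels = NULL) {
  stopifnot(length(summaries) >= 1)
  if (is.null(labels)) labels <- as.character(seq_along(summaries))
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    stopifnot(inherits(s, "response_summary"))
    pc <- s$proportion_correct
    rbind(data.frame(condition = labels[i], type = "correct",
                     response_prob = pc, quantile = .RT_QUANTILES,
                     rt = unname(s$rt_quantiles_correct)),
          data.frame(condition = labels[i], type = "error",
                     response_prob = 1 - pc, quantile = .RT_QUANTILES,
                     rt = unname(s$rt_quantiles_error)))
  })
  do.call(rbind, rows)
}

#' Paired correct/error RT percentiles for a quantile-quantile plot
#'
#' Matches the 1st..100th percentiles of correct and error RTs, dropping
#' pairs in which either percentile exceeds the cap (very long RTs are
#' excluded, 1.2 s by default). Points below the diagonal (error slower than
#' correct) indicate slow errors; above, fast errors.
#'
#' @param rt_correct,rt_error Non-empty numeric vectors of decided-trial
#'   RTs in seconds.
#' @param cap Exclusion threshold in seconds.
#' @return A data frame with columns `percentile`, `rt_correct`,
#'   `rt_error` (at most 100 rows).
#' @export
qq_percentiles <- function(rt_correct, rt_error, cap = 1.2) {
  if (!length(rt_correct) || !length(rt_error))
    stop("both RT sets must be non-empty", call. = FALSE)
  p <- (1:100) / 100
  qc <- stats::quantile(rt_correct, p, names = FALSE)
  qe <- stats::quantile(rt_error, p, names = FALSE)
  keep <- qc <= cap & qe <= cap
  data.frame(percentile = (1:100)[keep], rt_correct = qc[keep],
             rt_error = qe[keep])
}

#' Write a sweep result as tidy delimited text
#'
#' @param sweep A `sweep_result` data frame.
#' @param path Output file path.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}
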