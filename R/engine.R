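## Shared vectorized first-passage engine.
##
## Both the pDDM accumulator and the two-alternative BM posterior log-odds are
## random walks with i.i.d. Gaussian increments and symmetric absorbing
## thresholds, so one stepping loop serves all DDM-equivalent simulators. All
## trials advance together; decided trials drop out of the active set.

# n trials; per-trial start, threshold (> 0), increment mean and sd; walk for
# at most n_steps. Returns crossing step (NA if none) and whether the upper
# threshold was hit. Crossing at equality counts as a decision.
.walk_gaussian <- function(n, start, threshold, inc_mean, inc_sd, n_steps) {
  start <- rep_len(start, n)
  threshold <- rep_len(threshold, n)
  inc_mean <- rep_len(inc_mean, n)
  inc_sd <- rep_len(inc_sd, n)
  step <- rep(NA_integer_, n)
  upper <- rep(NA, n)
  y <- start
  active <- which(abs(start) < threshold)
  # degenerate starts at/over threshold decide immediately (step 0)
  if (length(active) < n) {
    hit0 <- setdiff(seq_len(n), active)
    step[hit0] <- 0L
    upper[hit0] <- y[hit0] > 0
  }
  k <- 0L
  while (length(active) && k < n_steps) {
    k <- k + 1L
    y[active] <- y[active] +
      stats::rnorm(length(active), inc_mean[active], inc_sd[active])
    hit <- abs(y[active]) >= threshold[active]
    if (any(hit)) {
      idx <- active[hit]
      step[idx] <- k
      upper[idx] <- y[idx] > 0
      active <- active[!hit]
    }
  }
  list(step = step, upper = upper, final = y)
}

# Deterministic-increment variant for exact-input models: increments are given
# as an n x T matrix (already in log-odds units), no sampling inside.
.walk_given_increments <- function(start, threshold, inc) {
  n <- nrow(inc)
  n_steps <- ncol(inc)
  start <- rep_len(start, n)
  threshold <- rep_len(threshold, n)
  step <- rep(NA_integer_, n)
  upper <- rep(NA, n)
  y <- start
  active <- which(abs(start) < threshold)
  if (length(active) < n) {
    hit0 <- setdiff(seq_len(n), active)
    step[hit0] <- 0L
    upper[hit0] <- y[hit0] > 0
  }
  k <- 0L
  while (length(active) && k < n_steps) {
    k <- k + 1L
    y[active] <- y[active] + inc[active, k]
    hit <- abs(y[active]) >= threshold[active]
    if (any(hit)) {
      idx <- active[hit]
      step[idx] <- k
      upper[idx] <- y[idx] > 0
      active <- active[!hit]
    }
  }
  list(step = step, upper = upper, final = y)
}

# Assemble a response_set data.frame from walk output.
.assemble_responses <- function(walk, dt, ndt, max_rt, condition,
                                true_choice) {
  n <- length(walk$step)
  decided <- !is.na(walk$step)
  rt <- rep(NA_real_, n)
  rt[decided] <- walk$step[decided] * dt + ndt[decided]
  choice <- ifelse(walk$upper, 1L, 2L)
  choice[!decided] <- NA_integer_
  timed_out <- !decided | (decided & rt > max_rt)
  rt[timed_out] <- max_rt
  response_set(choice = choice, rt = rt, timed_out = timed_out,
               condition = condition, true_choice = true_choice)
}

#' Construct a response set
#'
#' A `response_set` is the common output container of all simulators: a
#' data frame with one row per trial holding the chosen alternative, the
#' response time in seconds, a timeout flag, an arbitrary condition label and
#' (when known) the true alternative, from which correctness is derived.
#'
#' @param choice Integer vector of chosen alternatives (1 or 2; NA for
#'   timed-out trials without a choice).
#' @param rt Response times in seconds; timed-out trials carry the timeout
#'   cap.
#' @param timed_out Logical vector.
#' @param condition Condition label (recycled).
#' @param true_choice Optional integer vector of correct alternatives
#'   (recycled); NA if unknown.
#' @return A data frame of class `response_set` with columns `trial`,
#'   `condition`, `choice`, `rt`, `timed_out`, `true_choice`.
#' @export
response_set <- function(choice, rt, timed_out, condition = "default",
                         true_choice = NA_integer_) {
  n <- length(rt)
  if (length(choice) != n || length(timed_out) != n)
    stop("choice, rt and timed_out must have equal length", call. = FALSE)
  if (any(rt[!timed_out] <= 0, na.rm = TRUE))
    stop("decided trials must have rt > 0", call. = FALSE)
  out <- data.frame(trial = seq_len(n),
                    condition = rep_len(as.character(condition), n),
                    choice = as.integer(choice),
                    rt = as.numeric(rt),
                    timed_out = as.logical(timed_out),
                    true_choice = rep_len(as.integer(true_choice), n))
  class(out) <- c("response_set", "data.frame")
  out
}

# Uniform non-decision-time samples, truncated at zero.
.sample_ndt <- function(n, mean, spread) {
  if (spread == 0) return(rep(mean, n))
  pmax(0, stats::runif(n, mean - spread / 2, mean + spread / 2))
}
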