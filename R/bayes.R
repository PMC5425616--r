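## Core Bayesian model: input process, generative models, recursive
## accumulation, bound policy, lapses.

#' Internal uncertainty implied by a noise level
#'
#' The BM couples the width of the decision maker's generative models (the
#' internal uncertainty sigma-hat) to the sensory noise level sigma so that
#' the model is exactly equivalent to a DDM with diffusion rate `s`:
#' `sigma_hat^2 = sigma * |mu1 - mu2| / (dt * s)`.
#'
#' @param noise Noise level sigma (> 0).
#' @param s Diffusion constant of the equivalent DDM (> 0), default 2.8.
#' @param mu1,mu2 Generative-model means of the two alternatives (must
#'   differ).
#' @param dt Step length in seconds.
#' @return The internal uncertainty sigma-hat (standard deviation, > 0).
#' @export
#' @examples
#' internal_uncertainty_from_noise(1, 1, 1, -1, 1)^2 # = 2
internal_uncertainty_from_noise <- function(noise, s = 2.8, mu1, mu2, dt) {
  .check_num(noise, "noise", lower = 0, strict_lower = TRUE)
  .check_num(s, "s", lower = 0, strict_lower = TRUE)
  .check_num(dt, "dt", lower = 0, strict_lower = TRUE)
  if (!is.finite(mu1) || !is.finite(mu2) || mu1 == mu2)
    stop("generative means are degenerate (mu1 == mu2)", call. = FALSE)
  sqrt(noise * abs(mu1 - mu2) / (dt * s))
}

#' Construct an input sequence
#'
#' Per-trial sequence of sensory feature values with its time step and (if
#' known) the identity of the generating alternative.
#'
#' @param features Numeric vector of feature values, one per time step.
#' @param dt Time step in seconds.
#' @param true_alternative Index of the generating alternative (or NA).
#' @return An object of class `input_sequence`.
#' @export
input_sequence <- function(features, dt, true_alternative = NA_integer_) {
  if (!is.numeric(features) || length(features) < 1 || anyNA(features) ||
      any(!is.finite(features)))
    stop("features must be a non-empty finite numeric vector", call. = FALSE)
  .check_num(dt, "dt", lower = 0, strict_lower = TRUE)
  structure(list(features = as.numeric(features), dt = dt,
                 true_alternative = as.integer(true_alternative)),
            class = "input_sequence")
}

#' Sample a sensory input sequence
#'
#' Draws i.i.d. Gaussian feature values with mean `mu` (the feature mean of
#' the generating alternative) and variance `dt * noise^2`, the BM's model of
#' the noisy stimulus stream.
#'
#' @param mu Mean feature value of the generating alternative.
#' @param noise Noise level sigma (>= 0; zero returns the mean exactly).
#' @param dt Time step in seconds.
#' @param n_steps Number of steps (>= 1).
#' @param true_alternative Stored in the result for bookkeeping.
#' @return An [input_sequence()].
#' @export
sample_input_sequence <- function(mu, noise, dt, n_steps,
                                  true_alternative = NA_integer_) {
  stopifnot(n_steps >= 1)
  .check_num(noise, "noise", lower = 0)
  x <- if (noise == 0) rep(mu, n_steps)
       else stats::rnorm(n_steps, mu, sqrt(dt) * noise)
  input_sequence(x, dt, true_alternative)
}

#' Per-alternative Gaussian log likelihoods of one observation
#'
#' Scores a feature value under each alternative's generative model
#' `Normal(gen_means[i], dt * uncertainty^2)`. No normalization across
#' alternatives is applied.
#'
#' @param x A single feature value (finite).
#' @param gen_means Vector of generative-model means, one per alternative.
#' @param uncertainty Internal uncertainty sigma-hat (> 0).
#' @param dt Time step in seconds.
#' @return Numeric vector of log densities, one per alternative.
#' @export
log_likelihoods <- function(x, gen_means, uncertainty, dt) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop("x must be a single finite feature value", call. = FALSE)
  .check_num(uncertainty, "uncertainty", lower = 0, strict_lower = TRUE)
  stats::dnorm(x, mean = gen_means, sd = sqrt(dt) * uncertainty, log = TRUE)
}

#' Bayesian posterior update over alternatives
#'
#' One step of the recursive accumulation: the previous posterior is
#' multiplied elementwise by the per-alternative likelihoods and
#' renormalized. Carried out in log space (subtracting the maximum before
#' exponentiating) so that long streaks of one-sided evidence cannot
#' underflow.
#'
#' @param posterior Probability vector over alternatives (sums to 1).
#' @param log_lik Per-alternative log likelihoods of the new observation.
#' @return Updated probability vector.
#' @export
update_posterior <- function(posterior, log_lik) {
  if (abs(sum(posterior) - 1) > 1e-8 || any(posterior < 0))
    stop("posterior must be a probability vector", call. = FALSE)
  if (length(log_lik) != length(posterior))
    stop("posterior and log_lik lengths differ", call. = FALSE)
  lp <- log(posterior) + log_lik
  lp <- lp - max(lp[is.finite(lp) | posterior > 0], na.rm = TRUE)
  p <- exp(lp)
  p[posterior == 0] <- 0 # absorbing zero prior mass
  p / sum(p)
}

#' Run one BM trial on a given input sequence
#'
#' Reference (per-trial, any number of alternatives) implementation of the
#' accumulation: the posterior starts at the prior, consumes one observation
#' per step, and a decision is made at the first step where the maximum
#' posterior reaches the bound; the choice is the argmax (lowest index on
#' ties). The response time is the crossing step times `dt` plus a uniform
#' non-decision-time sample. Trials undecided when the input ends, or whose
#' RT would exceed `max_rt`, are timed out.
#'
#' @param params A [bm_params()] object. For more than two alternatives,
#'   supply a `prior` attribute via `prior_vec`.
#' @param input An [input_sequence()]; its `dt` must match `params$dt`.
#' @param prior_vec Optional explicit prior probability vector (length M);
#'   defaults to `c(prior, 1 - prior)`.
#' @return A list with `choice`, `rt`, `timed_out` and `trace`, a matrix of
#'   per-step posteriors (rows: steps 0..t) plus the decision step.
#' @export
#' @examples
#' b <- bm_params(bound = 0.8, noise = 222.5538, feature_means = c(25, -25))
#' inp <- sample_input_sequence(25, b$noise, b$dt, 100, 1)
#' set.seed(1); run_bm_trial(b, inp)$choice
run_bm_trial <- function(params, input, prior_vec = NULL) {
  stopifnot(inherits(params, "bm_params"), inherits(input, "input_sequence"))
  if (abs(input$dt - params$dt) > 1e-12)
    stop("input dt does not match model dt", call. = FALSE)
  m <- length(params$gen_means)
  if (is.null(prior_vec)) prior_vec <- c(params$prior, 1 - params$prior)
  if (length(prior_vec) != m)
    stop("prior_vec length must match the number of alternatives",
         call. = FALSE)
  log_post <- log(prior_vec)
  trace <- matrix(NA_real_, nrow = length(input$features) + 1, ncol = m)
  trace[1, ] <- prior_vec
  decision_step <- NA_integer_
  choice <- NA_integer_
  for (k in seq_along(input$features)) {
    ll <- log_likelihoods(input$features[k], params$gen_means,
                          params$uncertainty, params$dt)
    log_post <- log_post + ll
    log_post <- log_post - max(log_post)
    post <- exp(log_post) / sum(exp(log_post))
    trace[k + 1, ] <- post
    if (max(post) >= params$bound) {
      decision_step <- k
      choice <- which.max(post)
      break
    }
  }
  tnd <- .sample_ndt(1, params$ndt, params$ndt_spread)
  if (is.na(decision_step)) {
    return(list(choice = NA_integer_, rt = params$max_rt, timed_out = TRUE,
                trace = list(posteriors = trace,
                             decision_step = NA_integer_)))
  }
  rt <- decision_step * params$dt + tnd
  timed_out <- rt > params$max_rt
  list(choice = if (timed_out) NA_integer_ else choice,
       rt = min(rt, params$max_rt), timed_out = timed_out,
       trace = list(posteriors = trace[seq_len(decision_step + 1), ,
                                       drop = FALSE],
                    decision_step = decision_step))
}

#' Apply the lapse model to simulated responses
#'
#' With probability `lapse_prob` a trial becomes a lapse: its choice is
#' redrawn uniformly over the alternatives and its RT uniformly on
#' `(0, max_rt)`. A lapse is additionally converted to a timeout with
#' probability `timeout_lapse_prob`, so timed-out lapses occur with joint
#' probability `lapse_prob * timeout_lapse_prob`.
#'
#' @param responses A [response_set()].
#' @param lapse_prob,timeout_lapse_prob Probabilities in `[0, 1]`.
#' @param max_rt Timeout cap in seconds.
#' @param n_alternatives Number of response alternatives (default 2).
#' @return The modified [response_set()].
#' @export
apply_lapse <- function(responses, lapse_prob, timeout_lapse_prob, max_rt,
                        n_alternatives = 2) {
  stopifnot(inherits(responses, "response_set"))
  .check_num(lapse_prob, "lapse_prob", lower = 0, upper = 1)
  .check_num(timeout_lapse_prob, "timeout_lapse_prob", lower = 0, upper = 1)
  if (lapse_prob == 0) return(responses)
  n <- nrow(responses)
  is_lapse <- stats::runif(n) < lapse_prob
  k <- sum(is_lapse)
  if (k == 0) return(responses)
  responses$choice[is_lapse] <- sample.int(n_alternatives, k, replace = TRUE)
  responses$rt[is_lapse] <- stats::runif(k, 0, max_rt)
  responses$timed_out[is_lapse] <- FALSE
  to <- is_lapse & (stats::runif(n) < timeout_lapse_prob)
  responses$timed_out[to] <- TRUE
  responses$rt[to] <- max_rt
  responses$choice[to] <- NA_integer_
  responses
}

# Vectorized two-alternative DDM-equivalent fast path shared by simulate_bm
# and simulate_ebm. The posterior log-odds L = log(p1/p2) is a Gaussian
# random walk: increment = a*x_t + b with a = (mu1h - mu2h)/(dt*sigma_hat^2),
# b = -(mu1h^2 - mu2h^2)/(2*dt*sigma_hat^2), x_t ~ N(input_mean, dt*noise^2).
# All arguments may be per-trial vectors.
.sim_bm_batch <- function(n, bound, noise, uncertainty, prior, input_mean,
                          gen_means, dt, max_rt, ndt_mean, ndt_spread) {
  a <- (gen_means[1] - gen_means[2]) / (dt * uncertainty^2)
  b <- -(gen_means[1]^2 - gen_means[2]^2) / (2 * dt * uncertainty^2)
  inc_mean <- a * input_mean + b
  inc_sd <- abs(a) * sqrt(dt) * noise
  start <- stats::qlogis(prior)
  threshold <- stats::qlogis(bound)
  ndt_mean <- rep_len(ndt_mean, n)
  tnd <- if (ndt_spread == 0) ndt_mean
         else pmax(0, stats::runif(n, ndt_mean - ndt_spread / 2,
                                   ndt_mean + ndt_spread / 2))
  n_steps <- floor(max_rt / dt)
  walk <- .walk_gaussian(n, start = start, threshold = threshold,
                         inc_mean = inc_mean, inc_sd = inc_sd,
                         n_steps = n_steps)
  list(walk = walk, tnd = tnd)
}

#' Simulate the Bayesian model (DDM-equivalent input)
#'
#' Batch simulation of the BM with a fixed mean input per trial: trials
#' alternate between the two alternatives (balanced) unless
#' `true_alternative` pins them to one, and each trial's feature stream is
#' Gaussian around the corresponding feature mean. Decisions follow the
#' bound policy; lapses are applied afterwards.
#'
#' @param params A [bm_params()] object.
#' @param n_trials Number of trials.
#' @param seed Optional integer seed.
#' @param condition Condition label.
#' @param true_alternative Either `NULL` (balanced design alternating 1, 2)
#'   or a single alternative index used for every trial.
#' @return A [response_set()].
#' @export
#' @examples
#' b <- bm_params(bound = 0.8, noise = 222.5538, ndt = 0.4, ndt_spread = 0.2)
#' r <- simulate_bm(b, 2000, seed = 1)
#' mean((r$choice == r$true_choice)[!r$timed_out])
simulate_bm <- function(params, n_trials, seed = NULL, condition = "bm",
                        true_alternative = NULL) {
  stopifnot(inherits(params, "bm_params"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  truth <- if (is.null(true_alternative))
    rep_len(c(1L, 2L), n_trials) else rep(as.integer(true_alternative),
                                          n_trials)
  input_mean <- params$feature_means[truth]
  sim <- .sim_bm_batch(n_trials, params$bound, params$noise,
                       params$uncertainty, params$prior, input_mean,
                       params$gen_means, params$dt, params$max_rt,
                       params$ndt, params$ndt_spread)
  out <- .assemble_responses(sim$walk, dt = params$dt, ndt = sim$tnd,
                             max_rt = params$max_rt, condition = condition,
                             true_choice = truth)
  apply_lapse(out, params$lapse_prob, params$timeout_lapse_prob,
              params$max_rt)
}
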