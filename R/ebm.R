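## Extended Bayesian model: inter-trial variability of noise level (inverse
## Gaussian) and prior (uniform), plus the input-flip mechanism that mirrors
## negative drift-rate samples.

#' Inverse Gaussian random numbers
#'
#' Exact sampler via the Michael-Schucany-Haas transformation (one normal and
#' one uniform draw per sample, no rejection loop).
#'
#' @param n Number of draws.
#' @param mean Distribution mean (> 0); recycled if shorter than `n`.
#' @param shape Shape parameter lambda (> 0, recycled); the variance is
#'   `mean^3 / shape`.
#' @return Numeric vector of strictly positive draws.
#' @export
rinvgauss <- function(n, mean, shape) {
  if (any(!is.finite(mean)) || any(mean <= 0) ||
      any(!is.finite(shape)) || any(shape <= 0))
    stop("mean and shape must be positive and finite", call. = FALSE)
  mean <- rep_len(mean, n)
  shape <- rep_len(shape, n)
  y <- stats::rnorm(n)^2
  # smaller root of the MSH quadratic, in rationalized form: the textbook
  # mu*(1 + s - sqrt(s^2 + 2s)) with s = mu*y/(2*shape) cancels
  # catastrophically for small shape and can round to <= 0
  s <- mean * y / (2 * shape)
  x <- mean / (1 + s + sqrt(s^2 + 2 * s))
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Inverse Gaussian density
#'
#' @param x Evaluation points (> 0 has support; density is 0 elsewhere).
#' @param mean,shape As in [rinvgauss()].
#' @param log Return the log density?
#' @return Density values.
#' @export
dinvgauss <- function(x, mean, shape, log = FALSE) {
  out <- rep(-Inf, length(x))
  ok <- x > 0
  out[ok] <- 0.5 * (log(shape) - log(2 * pi) - 3 * log(x[ok])) -
    shape * (x[ok] - mean)^2 / (2 * mean^2 * x[ok])
  if (log) out else exp(out)
}

#' Sample a trial's noise level
#'
#' In the eBM the noise level of each trial is an inverse Gaussian draw with
#' mean `mean_noise` and shape `1/noise_var`, so its variance is
#' `mean_noise^3 * noise_var`. `noise_var = 0` returns the mean exactly.
#'
#' @param mean_noise Mean noise level (> 0).
#' @param noise_var Noise-level variability eta_N (>= 0).
#' @param n Number of draws.
#' @return Numeric vector of positive noise levels.
#' @export
sample_trial_noise_level <- function(mean_noise, noise_var, n = 1) {
  .check_num(mean_noise, "mean_noise", lower = 0, strict_lower = TRUE)
  .check_num(noise_var, "noise_var", lower = 0)
  if (noise_var == 0) return(rep(mean_noise, n))
  rinvgauss(n, mean = mean_noise, shape = 1 / noise_var)
}

#' Probability of a flipped input
#'
#' Approximates, for the eBM, the probability that a trial's effective mean
#' input points to the wrong alternative -- the analogue of a negative
#' drift-rate sample in the eDDM. Matching the mean-to-sd ratio of the
#' inverse Gaussian noise distribution to the Gaussian drift distribution
#' gives `P = Phi(-1 / sqrt(mean_noise * noise_var))`, which is 0 when
#' `noise_var = 0`.
#'
#' @param mean_noise Mean noise level (> 0).
#' @param noise_var Noise-level variability (>= 0).
#' @return Flip probability in `[0, 0.5)`.
#' @export
#' @examples
#' flip_probability(16.5, 0.023) # about 0.052
flip_probability <- function(mean_noise, noise_var) {
  .check_num(mean_noise, "mean_noise", lower = 0, strict_lower = TRUE)
  .check_num(noise_var, "noise_var", lower = 0)
  if (noise_var == 0) return(0)
  stats::pnorm(-1 / sqrt(mean_noise * noise_var))
}

#' Sample a trial's prior
#'
#' Uniform draw on `mean_prior +/- prior_spread/2`; a zero spread returns the
#' mean. The spread must respect `prior_spread < 2 * (bound - mean_prior)` so
#' no sampled prior can start at the decision bound; that constraint is
#' enforced at parameter construction ([ebm_params()]) and re-checked here
#' when a bound is supplied.
#'
#' @param mean_prior Mean prior probability.
#' @param prior_spread Full width of the uniform distribution (>= 0).
#' @param n Number of draws.
#' @param bound Optional decision bound for constraint checking.
#' @return Numeric vector of prior probabilities.
#' @export
sample_trial_prior <- function(mean_prior, prior_spread, n = 1,
                               bound = NULL) {
  .check_num(mean_prior, "mean_prior", lower = 0, upper = 1,
             strict_lower = TRUE, strict_upper = TRUE)
  .check_num(prior_spread, "prior_spread", lower = 0)
  if (!is.null(bound) &&
      (prior_spread >= 2 * (bound - mean_prior) ||
       prior_spread >= 2 * (bound - (1 - mean_prior))))
    stop("prior_spread must be < 2 * (bound - mean_prior)", call. = FALSE)
  if (prior_spread == 0) return(rep(mean_prior, n))
  stats::runif(n, mean_prior - prior_spread / 2,
               mean_prior + prior_spread / 2)
}

#' Simulate the extended Bayesian model (eBM / eEXaM)
#'
#' Per trial the model (i) draws a noise level from the inverse Gaussian
#' variability distribution and recomputes the internal uncertainty from it,
#' (ii) draws a prior from the uniform variability distribution, (iii) flips
#' the sign of the trial's mean input with the probability implied by the
#' noise variability ([flip_probability()]), (iv) draws a non-decision time,
#' runs the accumulation to the bound and (v) applies lapses.
#'
#' With `stimuli = NULL` the model runs in DDM-equivalent mode: the input
#' stream of a trial is Gaussian around the (possibly flipped) feature mean
#' of its true alternative. Supplying a [generate_dot_stimuli()] object
#' switches to exact-input mode (the eEXaM): each step consumes the actual
#' dot position of the corresponding stimulus frame, a flip negates the
#' whole feature sequence about the midpoint of the two targets, and the
#' model's `dt`, feature means and timeout are taken from the stimulus.
#'
#' @param params An [ebm_params()] object.
#' @param n_trials Number of trials (ignored in exact-input mode, where one
#'   trial is simulated per stimulus row).
#' @param seed Optional integer seed.
#' @param stimuli Optional `dot_stimuli` object for exact-input mode.
#' @param condition Condition label (defaults to the stimulus condition in
#'   exact-input mode).
#' @param true_alternative As in [simulate_bm()] (DDM-equivalent mode only).
#' @param diagnostics If `TRUE`, attach the per-trial sampled parameters
#'   (noise, prior, flipped, ndt) as attribute `"trial_params"`.
#' @return A [response_set()].
#' @export
#' @examples
#' e <- ebm_params(bound = 0.8, mean_noise = 222.5538, noise_var = 0.001,
#'                 prior_spread = 0.014, ndt = 0.4, ndt_spread = 0.2)
#' r <- simulate_ebm(e, 5000, seed = 11)
#' summarize_responses(r)$proportion_correct
simulate_ebm <- function(params, n_trials = NULL, seed = NULL,
                         stimuli = NULL, condition = NULL,
                         true_alternative = NULL, diagnostics = FALSE) {
  stopifnot(inherits(params, "ebm_params"))
  if (!is.null(seed)) set.seed(seed)
  exact <- !is.null(stimuli)
  if (exact) {
    stopifnot(inherits(stimuli, "dot_stimuli"))
    n_trials <- nrow(stimuli$frames)
    dt <- stimuli$frame_duration
    gen_means <- c(stimuli$target_offset, -stimuli$target_offset)
    max_rt <- ncol(stimuli$frames) * dt
    truth <- stimuli$true_target
    if (is.null(condition)) condition <- as.character(stimuli$condition)
  } else {
    stopifnot(n_trials >= 1)
    dt <- params$dt
    gen_means <- params$gen_means
    max_rt <- params$max_rt
    truth <- if (is.null(true_alternative)) rep_len(c(1L, 2L), n_trials)
             else rep(as.integer(true_alternative), n_trials)
    if (is.null(condition)) condition <- "ebm"
  }

  noise <- sample_trial_noise_level(params$mean_noise, params$noise_var,
                                    n_trials)
  uncertainty <- internal_uncertainty_from_noise(1, params$diffusion_scale,
                                                 gen_means[1], gen_means[2],
                                                 dt) * sqrt(noise)
  prior <- sample_trial_prior(params$mean_prior, params$prior_spread,
                              n_trials, bound = params$bound)
  p_flip <- flip_probability(params$mean_noise, params$noise_var)
  flipped <- stats::runif(n_trials) < p_flip
  sign_mult <- ifelse(flipped, -1, 1)
  tnd <- .sample_ndt(n_trials, params$ndt, params$ndt_spread)

  a <- (gen_means[1] - gen_means[2]) / (dt * uncertainty^2)
  b <- -(gen_means[1]^2 - gen_means[2]^2) / (2 * dt * uncertainty^2)
  start <- stats::qlogis(prior)
  threshold <- stats::qlogis(params$bound)

  if (exact) {
    mid <- mean(gen_means)
    x <- stimuli$frames
    x <- mid + sign_mult * (x - mid) # flip about the target midpoint
    inc <- a * x + b
    walk <- .walk_given_increments(start, threshold, inc)
  } else {
    input_mean <- sign_mult * params$feature_means[truth]
    inc_mean <- a * input_mean + b
    inc_sd <- abs(a) * sqrt(dt) * noise
    walk <- .walk_gaussian(n_trials, start = start, threshold = threshold,
                           inc_mean = inc_mean, inc_sd = inc_sd,
                           n_steps = floor(max_rt / dt))
  }
  out <- .assemble_responses(walk, dt = dt, ndt = tnd, max_rt = max_rt,
                             condition = condition, true_choice = truth)
  out <- apply_lapse(out, params$lapse_prob, params$timeout_lapse_prob,
                     max_rt)
  if (diagnostics)
    attr(out, "trial_params") <- data.frame(noise = noise, prior = prior,
                                            flipped = flipped, ndt = tnd)
  out
}

#' Simulate the exact-input Bayesian model (EXaM)
#'
#' BM variant whose per-step input is the actual stimulus feature sequence
#' (dot positions) instead of draws around a fixed mean; no inter-trial
#' parameter variability. Equivalent to [simulate_ebm()] with zero
#' variabilities in exact-input mode.
#'
#' @param params A [bm_params()] object; its noise level sets the internal
#'   uncertainty through the coupling, its `dt` is overridden by the frame
#'   duration.
#' @param stimuli A `dot_stimuli` object.
#' @param seed Optional integer seed.
#' @param condition Condition label.
#' @return A [response_set()].
#' @export
simulate_exam <- function(params, stimuli, seed = NULL, condition = NULL) {
  stopifnot(inherits(params, "bm_params"), inherits(stimuli, "dot_stimuli"))
  e <- ebm_params(bound = params$bound, mean_noise = params$noise,
                  noise_var = 0, mean_prior = params$prior,
                  prior_spread = 0, ndt = params$ndt,
                  ndt_spread = params$ndt_spread,
                  lapse_prob = params$lapse_prob,
                  timeout_lapse_prob = params$timeout_lapse_prob,
                  feature_means = params$feature_means,
                  gen_means = params$gen_means, dt = stimuli$frame_duration,
                  max_rt = ncol(stimuli$frames) * stimuli$frame_duration,
                  diffusion_scale = params$diffusion_scale)
  simulate_ebm(e, seed = seed, stimuli = stimuli, condition = condition)
}
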