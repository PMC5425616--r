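#' @keywords internal
"_PACKAGE"

## Parameter containers for the four model families. Plain lists with a class
## attribute and eager validation, in the style of survreg.control() et al.

.check_num <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE,
                       strict_upper = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric of length %d", name, len),
         call. = FALSE)
  ok <- if (strict_lower) all(x > lower) else all(x >= lower)
  ok <- ok && if (strict_upper) all(x < upper) else all(x <= upper)
  if (!ok)
    stop(sprintf("'%s' = %s outside its domain", name,
                 paste(signif(x, 6), collapse = ",")), call. = FALSE)
  x
}

#' Pure drift-diffusion model parameters
#'
#' The pDDM describes the decision variable as a discretized Wiener process:
#' at each step of length `dt` the accumulator moves by a Gaussian increment
#' with mean `drift * dt` and standard deviation `sqrt(dt) * diffusion`,
#' starting from `bias`, until it reaches one of the absorbing boundaries at
#' `+boundary` (choice 1) or `-boundary` (choice 2). A non-decision time is
#' added to the boundary-crossing time to form the response time.
#'
#' @param drift Drift rate (evidence units per second). Positive values favor
#'   alternative 1.
#' @param boundary Absorbing boundary height (> 0); bounds sit at
#'   `+/-boundary`.
#' @param bias Starting point, strictly inside `(-boundary, boundary)`.
#' @param ndt Non-decision time in seconds (>= 0).
#' @param diffusion Diffusion rate (> 0). Conventional scales are 0.1
#'   (classical DDM literature) or 2.8, which makes the equivalent Bayesian
#'   bound land near 0.8.
#' @param dt Step length in seconds (> 0).
#' @return An object of class `pddm_params`.
#' @seealso [simulate_pddm()], [pddm_to_bm()]
#' @export
#' @examples
#' p <- pddm_params(drift = 1.2, boundary = 1.4)
pddm_params <- function(drift, boundary, bias = 0, ndt = 0.3,
                        diffusion = 2.8, dt = 0.05) {
  .check_num(drift, "drift")
  .check_num(boundary, "boundary", lower = 0, strict_lower = TRUE)
  .check_num(bias, "bias", lower = -boundary, upper = boundary,
             strict_lower = TRUE, strict_upper = TRUE)
  .check_num(ndt, "ndt", lower = 0)
  .check_num(diffusion, "diffusion", lower = 0, strict_lower = TRUE)
  .check_num(dt, "dt", lower = 0, strict_lower = TRUE)
  structure(list(drift = drift, boundary = boundary, bias = bias, ndt = ndt,
                 diffusion = diffusion, dt = dt),
            class = "pddm_params")
}

#' Extended drift-diffusion model parameters
#'
#' The eDDM adds inter-trial variability to the pDDM: on each trial the drift
#' is drawn from `Normal(mean_drift, drift_sd)`, the starting point from
#' `Uniform(mean_bias +/- bias_spread/2)` and the non-decision time from
#' `Uniform(mean_ndt +/- ndt_spread/2)` (truncated at 0). The uniform bias
#' support must stay strictly inside the boundaries.
#'
#' @param mean_drift Mean drift rate across trials.
#' @param drift_sd Inter-trial standard deviation of the drift (>= 0).
#' @param boundary,diffusion,dt As in [pddm_params()].
#' @param mean_bias Mean starting point.
#' @param bias_spread Full width of the uniform starting-point distribution
#'   (>= 0); `mean_bias +/- bias_spread/2` must lie inside
#'   `(-boundary, boundary)`.
#' @param mean_ndt Mean non-decision time in seconds.
#' @param ndt_spread Full width of the uniform non-decision-time distribution
#'   (>= 0), with `mean_ndt - ndt_spread/2 >= 0`.
#' @return An object of class `eddm_params`.
#' @seealso [simulate_eddm()], [approximate_ebm_from_eddm()]
#' @export
eddm_params <- function(mean_drift, drift_sd = 0, boundary, mean_bias = 0,
                        bias_spread = 0, mean_ndt = 0.3, ndt_spread = 0,
                        diffusion = 2.8, dt = 0.05) {
  .check_num(mean_drift, "mean_drift")
  .check_num(drift_sd, "drift_sd", lower = 0)
  .check_num(boundary, "boundary", lower = 0, strict_lower = TRUE)
  .check_num(mean_bias, "mean_bias")
  .check_num(bias_spread, "bias_spread", lower = 0)
  lo <- mean_bias - bias_spread / 2
  hi <- mean_bias + bias_spread / 2
  if (lo <= -boundary || hi >= boundary)
    stop("bias support [", signif(lo, 4), ", ", signif(hi, 4),
         "] must lie strictly inside (-boundary, boundary)", call. = FALSE)
  .check_num(mean_ndt, "mean_ndt", lower = 0)
  .check_num(ndt_spread, "ndt_spread", lower = 0)
  if (mean_ndt - ndt_spread / 2 < 0)
    stop("mean_ndt - ndt_spread/2 must be >= 0", call. = FALSE)
  .check_num(diffusion, "diffusion", lower = 0, strict_lower = TRUE)
  .check_num(dt, "dt", lower = 0, strict_lower = TRUE)
  structure(list(mean_drift = mean_drift, drift_sd = drift_sd,
                 boundary = boundary, mean_bias = mean_bias,
                 bias_spread = bias_spread, mean_ndt = mean_ndt,
                 ndt_spread = ndt_spread, diffusion = diffusion, dt = dt),
            class = "eddm_params")
}

#' Bayesian model (BM) parameters
#'
#' The BM treats the decision as recursive Bayesian inference about which of
#' M alternatives generated a stream of noisy stimulus features. Features
#' arrive every `dt` seconds as draws from `Normal(mu_i, dt * noise^2)` where
#' `mu_i` is the feature mean of the true alternative; the decision maker
#' scores them under per-alternative Gaussian generative models with means
#' `gen_means` and standard deviation `uncertainty` (the internal
#' uncertainty), updates the posterior over alternatives, and commits as soon
#' as any posterior reaches `bound`. A (possibly variable) non-decision time
#' is added, and a fraction of trials can be replaced by random lapses.
#'
#' The internal uncertainty is not free: it is coupled to the noise level by
#' `uncertainty^2 = noise * |gen_means[1] - gen_means[2]| / (dt *
#' diffusion_scale)` (see [internal_uncertainty_from_noise()]), which is what
#' makes the model exactly equivalent to a pDDM with diffusion rate
#' `diffusion_scale`.
#'
#' @param bound Posterior decision bound, in `(0.5, 1)` for two alternatives.
#' @param noise Noise level sigma of the sensory input process (> 0), in
#'   feature units per sqrt(second).
#' @param prior Prior probability of alternative 1; both `prior` and
#'   `1 - prior` must be below `bound`.
#' @param ndt Mean non-decision time (seconds).
#' @param ndt_spread Full width of the uniform non-decision-time variability
#'   (seconds, >= 0); samples are truncated at 0.
#' @param lapse_prob Probability that a trial is a lapse: random choice and
#'   `Uniform(0, max_rt)` response time.
#' @param timeout_lapse_prob Probability that a lapse is additionally timed
#'   out, so timed-out lapses occur with rate `lapse_prob *
#'   timeout_lapse_prob`.
#' @param feature_means Numeric vector of per-alternative mean feature values
#'   (length M >= 2); the sweep experiments use `c(25, -25)`.
#' @param gen_means Means of the generative models; defaults to
#'   `feature_means` (the decision maker knows the task statistics).
#' @param dt Step length in seconds.
#' @param max_rt Timeout in seconds; responses that would exceed it are
#'   marked timed out.
#' @param diffusion_scale Fixed diffusion constant of the equivalent DDM used
#'   in the uncertainty coupling; 2.8 by default (0.1 reproduces the
#'   classical DDM scale).
#' @param uncertainty Optional explicit internal uncertainty; by default it
#'   is derived from `noise` via the coupling above.
#' @return An object of class `bm_params`.
#' @seealso [simulate_bm()], [run_bm_trial()], [bm_to_pddm()]
#' @export
#' @examples
#' b <- bm_params(bound = 0.8, noise = 222.5538, ndt = 0.4, ndt_spread = 0.2)
bm_params <- function(bound, noise, prior = 0.5, ndt = 0.3, ndt_spread = 0,
                      lapse_prob = 0, timeout_lapse_prob = 0,
                      feature_means = c(25, -25), gen_means = feature_means,
                      dt = 0.05, max_rt = 5, diffusion_scale = 2.8,
                      uncertainty = NULL) {
  .check_num(bound, "bound", lower = 0.5, upper = 1,
             strict_lower = TRUE, strict_upper = TRUE)
  .check_num(noise, "noise", lower = 0, strict_lower = TRUE)
  .check_num(prior, "prior", lower = 0, upper = 1,
             strict_lower = TRUE, strict_upper = TRUE)
  if (prior >= bound || (1 - prior) >= bound)
    stop("both prior and 1 - prior must be < bound, otherwise the model ",
         "decides before seeing any input", call. = FALSE)
  .check_num(ndt, "ndt", lower = 0)
  .check_num(ndt_spread, "ndt_spread", lower = 0)
  .check_num(lapse_prob, "lapse_prob", lower = 0, upper = 1)
  .check_num(timeout_lapse_prob, "timeout_lapse_prob", lower = 0, upper = 1)
  if (!is.numeric(feature_means) || length(feature_means) < 2)
    stop("feature_means must contain at least two alternatives", call. = FALSE)
  if (length(gen_means) != length(feature_means))
    stop("gen_means must have the same length as feature_means", call. = FALSE)
  .check_num(dt, "dt", lower = 0, strict_lower = TRUE)
  .check_num(max_rt, "max_rt", lower = dt, strict_lower = TRUE)
  .check_num(diffusion_scale, "diffusion_scale", lower = 0, strict_lower = TRUE)
  if (is.null(uncertainty))
    uncertainty <- internal_uncertainty_from_noise(noise, diffusion_scale,
                                                   gen_means[1], gen_means[2],
                                                   dt)
  else .check_num(uncertainty, "uncertainty", lower = 0, strict_lower = TRUE)
  structure(list(bound = bound, noise = noise, uncertainty = uncertainty,
                 prior = prior, ndt = ndt, ndt_spread = ndt_spread,
                 lapse_prob = lapse_prob,
                 timeout_lapse_prob = timeout_lapse_prob,
                 feature_means = feature_means, gen_means = gen_means,
                 dt = dt, max_rt = max_rt, diffusion_scale = diffusion_scale),
            class = "bm_params")
}

#' Extended Bayesian model (eBM) parameters
#'
#' The eBM adds inter-trial variability to the BM. On each trial the noise
#' level is drawn from an inverse Gaussian distribution with mean
#' `mean_noise` and shape `1/noise_var`, the internal uncertainty is
#' recomputed from the sampled noise level, the prior is drawn from
#' `Uniform(mean_prior +/- prior_spread/2)`, and with the flip probability
#' implied by `noise_var` (see [flip_probability()]) the sign of the mean
#' sensory input is flipped to the wrong alternative -- mirroring negative
#' drift-rate samples in the eDDM.
#'
#' @param mean_noise Mean noise level sigma-bar (> 0).
#' @param noise_var Noise-level variability eta_N (>= 0); the inverse
#'   Gaussian shape is `1/noise_var` and its variance is
#'   `mean_noise^3 * noise_var`. Zero switches variability off.
#' @param mean_prior Mean prior probability of alternative 1.
#' @param prior_spread Full width of the uniform prior variability (>= 0);
#'   must satisfy `prior_spread < 2 * (bound - mean_prior)` and the mirror
#'   constraint for alternative 2 so a sampled prior can never start at the
#'   bound.
#' @inheritParams bm_params
#' @return An object of class `ebm_params`.
#' @seealso [simulate_ebm()], [sample_trial_noise_level()],
#'   [sample_trial_prior()]
#' @export
#' @examples
#' e <- ebm_params(bound = 0.8, mean_noise = 222.5538, noise_var = 0.001,
#'                 prior_spread = 0.014, ndt = 0.4, ndt_spread = 0.2)
ebm_params <- function(bound, mean_noise, noise_var = 0, mean_prior = 0.5,
                       prior_spread = 0, ndt = 0.3, ndt_spread = 0,
                       lapse_prob = 0, timeout_lapse_prob = 0,
                       feature_means = c(25, -25), gen_means = feature_means,
                       dt = 0.05, max_rt = 5, diffusion_scale = 2.8) {
  .check_num(bound, "bound", lower = 0.5, upper = 1,
             strict_lower = TRUE, strict_upper = TRUE)
  .check_num(mean_noise, "mean_noise", lower = 0, strict_lower = TRUE)
  .check_num(noise_var, "noise_var", lower = 0)
  .check_num(mean_prior, "mean_prior", lower = 0, upper = 1,
             strict_lower = TRUE, strict_upper = TRUE)
  .check_num(prior_spread, "prior_spread", lower = 0)
  if (prior_spread >= 2 * (bound - mean_prior) ||
      prior_spread >= 2 * (bound - (1 - mean_prior)))
    stop("prior_spread must be < 2 * (bound - mean_prior) ",
         "(and its mirror for alternative 2)", call. = FALSE)
  base <- bm_params(bound = bound, noise = mean_noise, prior = mean_prior,
                    ndt = ndt, ndt_spread = ndt_spread,
                    lapse_prob = lapse_prob,
                    timeout_lapse_prob = timeout_lapse_prob,
                    feature_means = feature_means, gen_means = gen_means,
                    dt = dt, max_rt = max_rt,
                    diffusion_scale = diffusion_scale)
  out <- c(list(mean_noise = mean_noise, noise_var = noise_var,
                mean_prior = mean_prior, prior_spread = prior_spread),
           base[setdiff(names(base), c("noise", "prior", "uncertainty"))])
  structure(out, class = "ebm_params")
}

#' @export
print.pddm_params <- function(x, ...) {
  cat("pDDM parameters: drift", signif(x$drift, 4), "diffusion",
      signif(x$diffusion, 4), "boundary", signif(x$boundary, 4), "bias",
      signif(x$bias, 4), "ndt", signif(x$ndt, 4), "dt", x$dt, "\n")
  invisible(x)
}

#' @export
print.bm_params <- function(x, ...) {
  cat("BM parameters: bound", signif(x$bound, 4), "noise",
      signif(x$noise, 6), "uncertainty", signif(x$uncertainty, 6), "prior",
      signif(x$prior, 4), "ndt", signif(x$ndt, 4), "+/-",
      signif(x$ndt_spread / 2, 4), "\n")
  invisible(x)
}

#' @export
print.ebm_params <- function(x, ...) {
  cat("eBM parameters: bound", signif(x$bound, 4), "mean_noise",
      signif(x$mean_noise, 6), "noise_var", signif(x$noise_var, 4),
      "mean_prior", signif(x$mean_prior, 4), "prior_spread",
      signif(x$prior_spread, 4), "ndt", signif(x$ndt, 4), "+/-",
      signif(x$ndt_spread / 2, 4), "\n")
  invisible(x)
}
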