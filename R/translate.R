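## Exact equivalence mapping between the DDM family and the BM family, the
## change-of-variables densities for bias -> prior and drift -> noise level,
## and the uniform / inverse Gaussian approximation fit.

#' Translation context
#'
#' Bundles the constants of the drift <-> noise-level change of variables:
#' `c = diffusion * feature_mean / dt`, the scale constant such that the
#' trial's noise level is `c / drift`. `feature_mean` is the mean feature
#' value of the generating alternative, so `c` carries its sign.
#'
#' @param feature_mean Mean feature value of the true alternative (non-zero).
#' @param diffusion DDM diffusion constant (default 2.8; use 0.1 for the
#'   classical scale).
#' @param dt Step length in seconds.
#' @param gen_means Generative-model means of the two alternatives; default
#'   `c(feature_mean, -feature_mean)`.
#' @return An object of class `translation_context` with elements `c`,
#'   `feature_mean`, `diffusion`, `dt`, `gen_means`.
#' @export
translation_context <- function(feature_mean, diffusion = 2.8, dt = 0.05,
                                gen_means = c(feature_mean, -feature_mean)) {
  .check_num(feature_mean, "feature_mean")
  if (feature_mean == 0) stop("feature_mean must be non-zero", call. = FALSE)
  .check_num(diffusion, "diffusion", lower = 0, strict_lower = TRUE)
  .check_num(dt, "dt", lower = 0, strict_lower = TRUE)
  if (gen_means[1] == gen_means[2])
    stop("generative means must differ", call. = FALSE)
  structure(list(c = diffusion * feature_mean / dt,
                 feature_mean = feature_mean, diffusion = diffusion,
                 dt = dt, gen_means = gen_means),
            class = "translation_context")
}

#' Translate pDDM parameters to BM parameters
#'
#' The exact equivalence: bound `lambda = logistic(boundary)`, prior
#' `p0 = logistic(bias)`, noise level `sigma = c / drift` with
#' `c = diffusion * feature_mean / dt`, and internal uncertainty from the
#' coupling [internal_uncertainty_from_noise()]. Non-decision time is copied.
#' A negative drift makes the signed noise level negative, meaning the
#' trial's input points at the wrong alternative; the returned noise level
#' is its magnitude and the attribute `"flipped"` records the sign.
#'
#' @param p A [pddm_params()] object with non-zero drift.
#' @param context A [translation_context()]; its `dt` and `diffusion` must
#'   match `p`.
#' @param max_rt Timeout passed through to the BM parameters.
#' @return A [bm_params()] object with attribute `"flipped"`.
#' @export
#' @examples
#' p <- pddm_params(drift = 2, boundary = 1.3863, ndt = 0.4)
#' b <- pddm_to_bm(p, translation_context(25))
#' b$bound # logistic(1.3863) ~ 0.8
pddm_to_bm <- function(p, context, max_rt = 5) {
  stopifnot(inherits(p, "pddm_params"),
            inherits(context, "translation_context"))
  if (p$drift == 0)
    stop("drift = 0 has no finite noise-level translation", call. = FALSE)
  if (abs(p$dt - context$dt) > 1e-12 ||
      abs(p$diffusion - context$diffusion) > 1e-12)
    stop("context dt/diffusion must match the pDDM parameters",
         call. = FALSE)
  sigma_signed <- context$c / p$drift
  bm_params(bound = stats::plogis(p$boundary),
            noise = abs(sigma_signed),
            prior = stats::plogis(p$bias),
            ndt = p$ndt,
            feature_means = context$gen_means,
            gen_means = context$gen_means,
            dt = p$dt, max_rt = max_rt,
            diffusion_scale = p$diffusion) -> out
  attr(out, "flipped") <- sigma_signed < 0
  out
}

#' Translate BM parameters to pDDM parameters
#'
#' Algebraic inverse of [pddm_to_bm()]: `boundary = logit(bound)`,
#' `bias = logit(prior)`, `drift = c / noise`.
#'
#' @param b A [bm_params()] object with `0.5 < bound < 1` and
#'   `0 < prior < 1`.
#' @param context A [translation_context()] matching `b`'s `dt` and
#'   `diffusion_scale`.
#' @return A [pddm_params()] object.
#' @export
bm_to_pddm <- function(b, context) {
  stopifnot(inherits(b, "bm_params"),
            inherits(context, "translation_context"))
  if (abs(b$dt - context$dt) > 1e-12 ||
      abs(b$diffusion_scale - context$diffusion) > 1e-12)
    stop("context dt/diffusion must match the BM parameters", call. = FALSE)
  pddm_params(drift = context$c / b$noise,
              boundary = stats::qlogis(b$bound),
              bias = stats::qlogis(b$prior),
              ndt = b$ndt,
              diffusion = b$diffusion_scale,
              dt = b$dt)
}

#' Exact density of the prior under translated bias variability
#'
#' If the bias is uniform on `mean_bias +/- bias_spread/2` and the prior is
#' its logistic transform, the change of variables gives density
#' `1 / (bias_spread * (p - p^2))` on the transformed support and 0 outside.
#'
#' @param p Prior values at which to evaluate the density.
#' @param mean_bias,bias_spread Mean and full width of the uniform bias
#'   distribution (`bias_spread > 0`).
#' @return Density values.
#' @export
prior_density_exact <- function(p, mean_bias, bias_spread) {
  .check_num(bias_spread, "bias_spread", lower = 0, strict_lower = TRUE)
  lo <- stats::plogis(mean_bias - bias_spread / 2)
  hi <- stats::plogis(mean_bias + bias_spread / 2)
  out <- numeric(length(p))
  ok <- p >= lo & p <= hi
  out[ok] <- 1 / (bias_spread * (p[ok] - p[ok]^2))
  out
}

#' Exact CDF of the translated prior
#'
#' Companion to [prior_density_exact()] for goodness-of-fit testing:
#' `F(p) = (logit(p) - (mean_bias - bias_spread/2)) / bias_spread` on the
#' support.
#'
#' @inheritParams prior_density_exact
#' @return CDF values in `[0, 1]`.
#' @export
prior_cdf_exact <- function(p, mean_bias, bias_spread) {
  .check_num(bias_spread, "bias_spread", lower = 0, strict_lower = TRUE)
  z <- stats::qlogis(pmin(pmax(p, 1e-300), 1 - 1e-16))
  pmin(1, pmax(0, (z - (mean_bias - bias_spread / 2)) / bias_spread))
}

#' Exact density of the signed noise level under drift variability
#'
#' The noise level is `sigma = c / drift` with Gaussian drift
#' `Normal(mean_drift, drift_sd)`. The change of variables gives
#' `f(sigma) = dnorm(c/sigma; mean_drift, drift_sd) * |c| / sigma^2` over the
#' signed real line: for `c > 0`, positive sigma corresponds to positive
#' drift samples ("original input") and negative sigma to negative drift
#' samples ("flipped input").
#'
#' @param sigma Signed noise-level values (non-zero).
#' @param mean_drift,drift_sd Mean and standard deviation of the drift
#'   distribution (`drift_sd > 0`).
#' @param context A [translation_context()].
#' @return Density values on the signed support.
#' @export
noise_density_exact <- function(sigma, mean_drift, drift_sd, context) {
  stopifnot(inherits(context, "translation_context"))
  .check_num(drift_sd, "drift_sd", lower = 0, strict_lower = TRUE)
  out <- numeric(length(sigma))
  ok <- sigma != 0
  out[ok] <- stats::dnorm(context$c / sigma[ok], mean_drift, drift_sd) *
    abs(context$c) / sigma[ok]^2
  out
}

#' Exact CDF of the signed noise level
#'
#' Closed form companion to [noise_density_exact()] (requires `c > 0`): for
#' `s < 0`, `F(s) = Phi(0) - Phi(c/s)`; for `s > 0`,
#' `F(s) = Phi(0) + 1 - Phi(c/s)`, where `Phi` is the drift CDF.
#'
#' @param sigma Signed noise-level values.
#' @inheritParams noise_density_exact
#' @return CDF values in `[0, 1]`.
#' @export
noise_cdf_exact <- function(sigma, mean_drift, drift_sd, context) {
  stopifnot(inherits(context, "translation_context"))
  if (context$c <= 0)
    stop("noise_cdf_exact assumes c > 0 (positive feature mean)",
         call. = FALSE)
  p0 <- stats::pnorm(0, mean_drift, drift_sd)
  out <- numeric(length(sigma))
  neg <- sigma < 0
  pos <- sigma > 0
  out[neg] <- p0 - stats::pnorm(context$c / sigma[neg], mean_drift, drift_sd)
  out[sigma == 0] <- p0
  out[pos] <- p0 + 1 - stats::pnorm(context$c / sigma[pos], mean_drift,
                                    drift_sd)
  out
}

#' Probability of a negative drift sample
#'
#' `P(drift < 0) = Phi(-mean_drift / drift_sd)`, which depends only on the
#' mean-to-sd ratio. `drift_sd = 0` returns 0, 1 or 0.5 according to the
#' sign of the mean.
#'
#' @param mean_drift,drift_sd Drift distribution parameters (`drift_sd >=
#'   0`).
#' @return A probability.
#' @export
negative_drift_prob <- function(mean_drift, drift_sd) {
  .check_num(drift_sd, "drift_sd", lower = 0)
  if (drift_sd == 0)
    return(if (mean_drift < 0) 1 else if (mean_drift > 0) 0 else 0.5)
  stats::pnorm(-mean_drift / drift_sd)
}

#' Inverse Gaussian CDF
#'
#' @param q Quantiles (> 0 has support).
#' @param mean,shape As in [rinvgauss()].
#' @return CDF values.
#' @export
pinvgauss <- function(q, mean, shape) {
  out <- numeric(length(q))
  ok <- q > 0
  qq <- q[ok]
  a <- sqrt(shape / qq)
  out[ok] <- stats::pnorm(a * (qq / mean - 1)) +
    exp(2 * shape / mean + stats::pnorm(-a * (qq / mean + 1), log.p = TRUE))
  pmin(1, pmax(0, out))
}

#' Fit approximate eBM parameters from eDDM parameters
#'
#' Maps extended DDM variability to the eBM's standard-density
#' approximations:
#' \itemize{
#' \item prior: the exact translated density ([prior_density_exact()]) is
#'   replaced by a uniform whose support matches the exact support endpoints
#'   (`mean_prior` = midpoint, `prior_spread` = width);
#' \item noise level: an inverse Gaussian whose mean-to-sd ratio reproduces
#'   the drift distribution's ratio (so the flip probability of the
#'   approximation, [flip_probability()], equals the exact negative-drift
#'   probability, [negative_drift_prob()]), pinned down by matching the
#'   median of the exact density's positive branch. Median rather than mean
#'   matching is used because the positive branch of the exact density has
#'   infinite mean (the Gaussian drift has positive density at 0, and
#'   `sigma = c/drift` has a `1/sigma` tail).
#' }
#' Degenerate inputs (`drift_sd = 0` or `bias_spread = 0`) give zero-spread
#' eBM parameters.
#'
#' @param e An [eddm_params()] object.
#' @param context A [translation_context()] matching `e`.
#' @param max_rt Timeout stored in the result.
#' @return An [ebm_params()] object.
#' @export
#' @examples
#' e <- eddm_params(mean_drift = 2, drift_sd = 0.5, boundary = 1.3863,
#'                  bias_spread = 0.1, mean_ndt = 0.4)
#' a <- approximate_ebm_from_eddm(e, translation_context(25))
#' 1 / sqrt(a$mean_noise * a$noise_var) # = mean_drift / drift_sd
approximate_ebm_from_eddm <- function(e, context, max_rt = 5) {
  stopifnot(inherits(e, "eddm_params"),
            inherits(context, "translation_context"))
  if (abs(e$dt - context$dt) > 1e-12 ||
      abs(e$diffusion - context$diffusion) > 1e-12)
    stop("context dt/diffusion must match the eDDM parameters",
         call. = FALSE)
  if (e$mean_drift <= 0)
    stop("approximation assumes a positive mean drift", call. = FALSE)
  cc <- abs(context$c)

  # prior: support matching of the exact logistic-transformed support
  lo <- stats::plogis(e$mean_bias - e$bias_spread / 2)
  hi <- stats::plogis(e$mean_bias + e$bias_spread / 2)
  mean_prior <- (lo + hi) / 2
  prior_spread <- hi - lo

  if (e$drift_sd == 0) {
    mean_noise <- cc / e$mean_drift
    noise_var <- 0
  } else {
    ratio <- e$mean_drift / e$drift_sd # = 1 / sqrt(mean_noise * noise_var)
    # median of the positive branch of the exact signed density
    p_neg <- stats::pnorm(-ratio)
    med <- cc / stats::qnorm(p_neg + 0.5 * (1 - p_neg), e$mean_drift,
                             e$drift_sd)
    f <- function(m) pinvgauss(med, mean = m, shape = ratio^2 * m) - 0.5
    mean_noise <- stats::uniroot(f, lower = med, upper = med * 50,
                                 extendInt = "downX", tol = 1e-10)$root
    noise_var <- 1 / (ratio^2 * mean_noise)
  }
  ebm_params(bound = stats::plogis(e$boundary), mean_noise = mean_noise,
             noise_var = noise_var, mean_prior = mean_prior,
             prior_spread = prior_spread, ndt = e$mean_ndt,
             ndt_spread = e$ndt_spread, feature_means = context$gen_means,
             gen_means = context$gen_means, dt = e$dt, max_rt = max_rt,
             diffusion_scale = e$diffusion)
}

#' Simulate the eDDM through its exact BM translation
#'
#' Validation route for the equivalence: per trial, drift, bias and
#' non-decision time are sampled from the eDDM variability distributions and
#' pushed through the exact maps (noise level `c/drift` with a flipped input
#' when the drift sample is negative; prior `logistic(bias)`; internal
#' uncertainty from the coupling), then the BM accumulation runs on
#' Gaussian input. The response distribution should match [simulate_eddm()]
#' up to Monte-Carlo error.
#'
#' @param ext An [eddm_params()] object.
#' @param context A [translation_context()] matching `ext`.
#' @param n_trials Number of trials.
#' @param max_time Timeout in seconds.
#' @param seed Optional integer seed.
#' @param condition Condition label.
#' @return A [response_set()] with `true_choice = 1`.
#' @export
simulate_eddm_via_bm <- function(ext, context, n_trials, max_time = 5,
                                 seed = NULL, condition = "ebm-translated") {
  stopifnot(inherits(ext, "eddm_params"),
            inherits(context, "translation_context"))
  if (!is.null(seed)) set.seed(seed)
  v <- if (ext$drift_sd == 0) rep(ext$mean_drift, n_trials)
       else stats::rnorm(n_trials, ext$mean_drift, ext$drift_sd)
  v[v == 0] <- .Machine$double.eps # measure-zero guard
  z <- if (ext$bias_spread == 0) rep(ext$mean_bias, n_trials)
       else stats::runif(n_trials, ext$mean_bias - ext$bias_spread / 2,
                         ext$mean_bias + ext$bias_spread / 2)
  tnd <- .sample_ndt(n_trials, ext$mean_ndt, ext$ndt_spread)

  sigma_signed <- context$c / v
  noise <- abs(sigma_signed)
  flipped <- sigma_signed < 0
  gm <- context$gen_means
  uncertainty <- sqrt(noise * abs(gm[1] - gm[2]) /
                        (ext$dt * context$diffusion))
  prior <- stats::plogis(z)
  input_mean <- ifelse(flipped, -1, 1) * context$feature_mean

  a <- (gm[1] - gm[2]) / (ext$dt * uncertainty^2)
  b <- -(gm[1]^2 - gm[2]^2) / (2 * ext$dt * uncertainty^2)
  walk <- .walk_gaussian(n_trials, start = stats::qlogis(prior),
                         threshold = stats::qlogis(stats::plogis(ext$boundary)),
                         inc_mean = a * input_mean + b,
                         inc_sd = abs(a) * sqrt(ext$dt) * noise,
                         n_steps = floor(max_time / ext$dt))
  .assemble_responses(walk, dt = ext$dt, ndt = tnd, max_rt = max_time,
                      condition = condition, true_choice = 1L)
}
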