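## Likelihood-free fitting. Parameters live in an unconstrained Gaussian
## space and are mapped to model space by per-parameter transformations
## (exponential -> log-normal marginals; Gaussian-CDF -> bounded intervals).
## Two fitters share one ABC acceptance kernel (same choice, |rt difference|
## <= eps, timeouts matched on the flag): an importance-sampling fallback
## treating the trials of a condition as i.i.d., and trial-wise EP-ABC.

#' Prior specification for model fitting
#'
#' One row per free parameter: the transformation kind and the mean and sd
#' of the underlying Gaussian. Kinds: `"exp"` (log-normal marginal),
#' `"unif"` (Gaussian CDF then scaled to `[lower, upper]`; a standard normal
#' underlying Gaussian gives a flat marginal, other Gaussians a biased
#' bounded one), `"none"` (identity). Priors are a priori uncorrelated.
#'
#' @param param Character vector of parameter names.
#' @param kind Transformation kind per parameter.
#' @param mean,sd Underlying Gaussian moments.
#' @param lower,upper Target interval for the `"unif"` kind.
#' @return A data frame of class `prior_spec`.
#' @export
prior_spec <- function(param, kind, mean, sd, lower = 0, upper = 1) {
  kind <- match.arg(kind, c("exp", "unif", "none"), several.ok = TRUE)
  out <- data.frame(param = param, kind = rep_len(kind, length(param)),
                    mean = rep_len(mean, length(param)),
                    sd = rep_len(sd, length(param)),
                    lower = rep_len(lower, length(param)),
                    upper = rep_len(upper, length(param)),
                    stringsAsFactors = FALSE)
  if (any(out$sd <= 0)) stop("prior sds must be positive", call. = FALSE)
  class(out) <- c("prior_spec", "data.frame")
  out
}

#' Default fitting priors
#'
#' The standard priors for the model families: bound uniform(0,1) via a
#' standard normal; mean noise log-normal(5,1); noise variability
#' log-normal(-10,3); mean prior uniform(0,1); prior spread bounded on
#' (0,1) through a Normal(-2,1) (biased toward small spreads); non-decision
#' time log-normal(-1.5,1); its spread log-normal(-2,1); lapse probability
#' bounded through Normal(-1,1); timeout-lapse probability uniform(0,1).
#'
#' @param model `"bm"`/`"exam"` (7 parameters) or `"ebm"`/`"eexam"` (9,
#'   adding the two variability parameters).
#' @param free Optional character vector restricting the spec to a subset
#'   of parameters (the others are then fixed by the simulator factory).
#' @return A [prior_spec()].
#' @export
default_priors <- function(model = c("bm", "ebm", "exam", "eexam"),
                           free = NULL) {
  model <- match.arg(model)
  tab <- rbind(
    data.frame(param = "bound", kind = "unif", mean = 0, sd = 1,
               lower = 0, upper = 1),
    data.frame(param = "mean_noise", kind = "exp", mean = 5, sd = 1,
               lower = NA, upper = NA),
    data.frame(param = "noise_var", kind = "exp", mean = -10, sd = 3,
               lower = NA, upper = NA),
    data.frame(param = "mean_prior", kind = "unif", mean = 0, sd = 1,
               lower = 0, upper = 1),
    data.frame(param = "prior_spread", kind = "unif", mean = -2, sd = 1,
               lower = 0, upper = 1),
    data.frame(param = "ndt", kind = "exp", mean = -1.5, sd = 1,
               lower = NA, upper = NA),
    data.frame(param = "ndt_spread", kind = "exp", mean = -2, sd = 1,
               lower = NA, upper = NA),
    data.frame(param = "lapse_prob", kind = "unif", mean = -1, sd = 1,
               lower = 0, upper = 1),
    data.frame(param = "timeout_lapse_prob", kind = "unif", mean = 0,
               sd = 1, lower = 0, upper = 1))
  if (model %in% c("bm", "exam"))
    tab <- tab[!tab$param %in% c("noise_var", "prior_spread"), ]
  if (!is.null(free)) tab <- tab[tab$param %in% free, ]
  tab$lower[is.na(tab$lower)] <- 0
  tab$upper[is.na(tab$upper)] <- 1
  out <- tab
  class(out) <- c("prior_spec", "data.frame")
  rownames(out) <- NULL
  out
}

#' Transform Gaussian-space values to model space (and back)
#'
#' @param u Numeric vector (one value per spec row) or matrix (rows =
#'   draws) in the unconstrained Gaussian space.
#' @param spec A [prior_spec()].
#' @return Model-space values with the same shape.
#' @export
transform_parameters <- function(u, spec) {
  stopifnot(inherits(spec, "prior_spec"))
  f <- function(v) {
    out <- v
    for (j in seq_len(nrow(spec))) {
      out[j] <- switch(spec$kind[j],
        exp = exp(v[j]),
        unif = spec$lower[j] +
          (spec$upper[j] - spec$lower[j]) * stats::pnorm(v[j]),
        none = v[j])
    }
    stats::setNames(out, spec$param)
  }
  if (is.matrix(u)) {
    out <- t(apply(u, 1, f))
    colnames(out) <- spec$param
    out
  } else f(u)
}

#' @rdname transform_parameters
#' @param theta Model-space values.
#' @export
inverse_transform_parameters <- function(theta, spec) {
  stopifnot(inherits(spec, "prior_spec"))
  f <- function(v) {
    out <- v
    for (j in seq_len(nrow(spec))) {
      out[j] <- switch(spec$kind[j],
        exp = log(v[j]),
        unif = stats::qnorm((v[j] - spec$lower[j]) /
                              (spec$upper[j] - spec$lower[j])),
        none = v[j])
    }
    stats::setNames(out, spec$param)
  }
  if (is.matrix(theta)) t(apply(theta, 1, f)) else f(theta)
}

# --- simulator factories ----------------------------------------------------

#' Build a simulator for fitting
#'
#' Returns a closure used by the fitters. For the i.i.d. models (`"bm"`,
#' `"ebm"` in DDM-equivalent mode) the closure has signature
#' `function(theta, n, true_alternative)` and returns a [response_set()] of
#' `n` i.i.d. responses; invalid parameter combinations return `NULL`. The
#' closure also carries an attribute `"sim_one"` with signature
#' `function(theta_matrix, truth, stimulus_row)` that simulates exactly one
#' response per parameter draw (used by EP-ABC; supports `"exam"` /
#' `"eexam"` through the stimulus row).
#'
#' @param model Model name.
#' @param fixed Named list of parameter values held fixed (not fitted).
#' @param stimuli Optional `dot_stimuli` for the exact-input models.
#' @param feature_means Feature means for the DDM-equivalent models.
#' @param gen_means Generative-model means; defaults to `feature_means`.
#'   Setting them apart deliberately mis-specifies the observer (useful for
#'   dominated-model checks).
#' @param dt,max_rt Time step and timeout for the DDM-equivalent models.
#' @return A simulator closure.
#' @export
make_model_simulator <- function(model = c("bm", "ebm", "exam", "eexam"),
                                 fixed = list(), stimuli = NULL,
                                 feature_means = c(25, -25),
                                 gen_means = feature_means, dt = 0.05,
                                 max_rt = 5) {
  model <- match.arg(model)
  exact <- model %in% c("exam", "eexam")
  extended <- model %in% c("ebm", "eexam")
  if (exact && is.null(stimuli))
    stop("exact-input models need stimuli", call. = FALSE)
  defaults <- list(bound = 0.8, mean_noise = 100, noise_var = 0,
                   mean_prior = 0.5, prior_spread = 0, ndt = 0.3,
                   ndt_spread = 0, lapse_prob = 0, timeout_lapse_prob = 0)
  base <- utils::modifyList(defaults, fixed)

  build_params <- function(theta) {
    p <- utils::modifyList(base, as.list(theta))
    if (!extended) {
      p$noise_var <- 0
      if (!"prior_spread" %in% names(theta)) p$prior_spread <- 0
    }
    ok <- all(vapply(p, function(v) is.numeric(v) && all(is.finite(v)),
                     logical(1))) &&
      p$bound > 0.5 && p$bound < 1 && p$mean_noise > 0 &&
      p$mean_noise < 1e9 && p$mean_prior > 0 && p$mean_prior < 1 &&
      p$mean_prior < p$bound && (1 - p$mean_prior) < p$bound &&
      p$prior_spread < 2 * (p$bound - p$mean_prior) &&
      p$prior_spread < 2 * (p$bound - (1 - p$mean_prior)) &&
      p$ndt >= 0 && p$ndt < 1e6 && p$ndt_spread >= 0 &&
      p$ndt_spread < 1e6 && p$noise_var >= 0 && p$noise_var < 1e9
    if (!ok) return(NULL)
    ebm_params(bound = p$bound, mean_noise = p$mean_noise,
               noise_var = p$noise_var, mean_prior = p$mean_prior,
               prior_spread = p$prior_spread, ndt = p$ndt,
               ndt_spread = p$ndt_spread, lapse_prob = p$lapse_prob,
               timeout_lapse_prob = p$timeout_lapse_prob,
               feature_means = feature_means, gen_means = gen_means,
               dt = dt, max_rt = max_rt)
  }

  sim_iid <- function(theta, n, true_alternative = 1) {
    if (exact) stop("i.i.d. simulation undefined for exact-input models",
                    call. = FALSE)
    prm <- build_params(theta)
    if (is.null(prm)) return(NULL)
    simulate_ebm(prm, n, true_alternative = true_alternative)
  }

  # crossing times and choices only (non-decision time and lapses left to be
  # integrated analytically by the smoothed ABC kernel)
  sim_decisions <- function(theta, n, true_alternative = 1) {
    if (exact) stop("i.i.d. simulation undefined for exact-input models",
                    call. = FALSE)
    prm <- build_params(theta)
    if (is.null(prm)) return(NULL)
    noise <- sample_trial_noise_level(prm$mean_noise, prm$noise_var, n)
    unc2 <- noise * abs(prm$gen_means[1] - prm$gen_means[2]) /
      (prm$dt * prm$diffusion_scale)
    prior <- sample_trial_prior(prm$mean_prior, prm$prior_spread, n)
    pflip <- flip_probability(prm$mean_noise, prm$noise_var)
    sgn <- ifelse(stats::runif(n) < pflip, -1, 1)
    a <- (prm$gen_means[1] - prm$gen_means[2]) / (prm$dt * unc2)
    b <- -(prm$gen_means[1]^2 - prm$gen_means[2]^2) / (2 * prm$dt * unc2)
    input_mean <- sgn * prm$feature_means[true_alternative]
    walk <- .walk_gaussian(n, start = stats::qlogis(prior),
                           threshold = stats::qlogis(prm$bound),
                           inc_mean = a * input_mean + b,
                           inc_sd = abs(a) * sqrt(prm$dt) * noise,
                           n_steps = floor(prm$max_rt / prm$dt))
    list(dtime = walk$step * prm$dt,
         choice = ifelse(walk$upper, 1L, 2L),
         ndt = prm$ndt, ndt_spread = prm$ndt_spread,
         lapse_prob = prm$lapse_prob,
         timeout_lapse_prob = prm$timeout_lapse_prob,
         max_rt = prm$max_rt)
  }

  # one response per parameter draw, all for the same trial
  sim_one <- function(theta_mat, truth = 1, stimulus_row = NULL) {
    s <- nrow(theta_mat)
    get <- function(name) {
      if (name %in% colnames(theta_mat)) theta_mat[, name]
      else rep(base[[name]], s)
    }
    bound <- get("bound"); mean_noise <- get("mean_noise")
    noise_var <- if (extended) get("noise_var") else rep(0, s)
    mean_prior <- get("mean_prior")
    prior_spread <- if (extended) get("prior_spread") else rep(0, s)
    ndt <- get("ndt"); ndt_spread <- get("ndt_spread")
    lapse_prob <- get("lapse_prob")
    timeout_lapse_prob <- get("timeout_lapse_prob")
    valid <- is.finite(bound + mean_noise + noise_var + mean_prior +
                         prior_spread + ndt + ndt_spread) &
      bound > 0.5 & bound < 1 & mean_noise > 0 & mean_noise < 1e9 &
      mean_prior > 0 & mean_prior < 1 & mean_prior < bound &
      (1 - mean_prior) < bound &
      prior_spread < 2 * (bound - mean_prior) &
      prior_spread < 2 * (bound - (1 - mean_prior)) &
      ndt >= 0 & ndt < 1e6 & ndt_spread >= 0 & ndt_spread < 1e6 &
      noise_var >= 0 & noise_var < 1e9
    if (any(!valid)) { # park invalid rows on safe values; they never match
      bound[!valid] <- 0.8; mean_noise[!valid] <- 100
      noise_var[!valid] <- 0; mean_prior[!valid] <- 0.5
      prior_spread[!valid] <- 0; ndt[!valid] <- 0.3
      ndt_spread[!valid] <- 0; lapse_prob[!valid] <- 0
      timeout_lapse_prob[!valid] <- 0
    }

    this_dt <- if (exact) stimuli$frame_duration else dt
    this_max <- if (exact) ncol(stimuli$frames) * stimuli$frame_duration
                else max_rt
    gm <- if (exact) c(stimuli$target_offset, -stimuli$target_offset)
          else gen_means
    fm <- if (exact) gm else feature_means

    noise <- ifelse(noise_var > 0 & valid,
                    rinvgauss(s, pmax(mean_noise, 1e-12),
                              1 / pmax(noise_var, 1e-12)),
                    mean_noise)
    unc2 <- noise * abs(gm[1] - gm[2]) / (this_dt * 2.8)
    prior <- ifelse(prior_spread > 0,
                    stats::runif(s, mean_prior - prior_spread / 2,
                                 mean_prior + prior_spread / 2),
                    mean_prior)
    pflip <- ifelse(noise_var > 0,
                    stats::pnorm(-1 / sqrt(pmax(mean_noise * noise_var,
                                                1e-300))), 0)
    sgn <- ifelse(stats::runif(s) < pflip, -1, 1)
    tnd <- pmax(0, ifelse(ndt_spread > 0,
                          stats::runif(s, ndt - ndt_spread / 2,
                                       ndt + ndt_spread / 2), ndt))
    a <- (gm[1] - gm[2]) / (this_dt * unc2)
    b <- -(gm[1]^2 - gm[2]^2) / (2 * this_dt * unc2)
    start <- stats::qlogis(pmin(pmax(prior, 1e-12), 1 - 1e-12))
    threshold <- stats::qlogis(pmin(pmax(bound, 0.5 + 1e-12), 1 - 1e-12))
    if (exact) {
      x <- stimulus_row
      mid <- mean(gm)
      inc <- outer(a * sgn, x - mid) + (a * mid + b)
      walk <- .walk_given_increments(start, threshold, inc)
    } else {
      input_mean <- sgn * fm[truth]
      walk <- .walk_gaussian(s, start, threshold,
                             inc_mean = a * input_mean + b,
                             inc_sd = abs(a) * sqrt(this_dt) * noise,
                             n_steps = floor(this_max / this_dt))
    }
    decided <- !is.na(walk$step)
    rt <- ifelse(decided, walk$step * this_dt + tnd, this_max)
    choice <- ifelse(walk$upper, 1L, 2L)
    timed_out <- !decided | rt > this_max
    rt <- pmin(rt, this_max)
    # lapses
    lap <- stats::runif(s) < lapse_prob
    if (any(lap)) {
      choice[lap] <- sample.int(2L, sum(lap), replace = TRUE)
      rt[lap] <- stats::runif(sum(lap), 0, this_max)
      timed_out[lap] <- FALSE
      lto <- lap & stats::runif(s) < timeout_lapse_prob
      timed_out[lto] <- TRUE
      rt[lto] <- this_max
    }
    choice[timed_out] <- NA_integer_
    data.frame(choice = choice, rt = rt, timed_out = timed_out,
               valid = valid)
  }

  structure(sim_iid, sim_one = sim_one, sim_decisions = sim_decisions,
            model = model, class = c("ebdm_simulator", "function"))
}

# --- ABC kernel -------------------------------------------------------------

# Per-trial log acceptance probabilities of a data set under K reference
# simulations (shared across trials of the same true alternative). Non-timeout
# trials get a density via the 1/(2*eps) kernel normalization; estimated
# probabilities are floored at 0.5/K to keep the log finite.
.kernel_loglik <- function(data, ref_by_truth, eps) {
  total <- 0
  for (g in names(ref_by_truth)) {
    ref <- ref_by_truth[[g]]
    k <- nrow(ref)
    rows <- if (g == "any") seq_len(nrow(data))
            else which(as.character(data$true_choice) == g)
    if (!length(rows)) next
    floor_p <- 0.5 / k
    p_to <- max(mean(ref$timed_out), floor_p)
    sorted <- lapply(1:2, function(ch)
      sort(ref$rt[!ref$timed_out & ref$choice == ch]))
    for (j in rows) {
      if (data$timed_out[j]) {
        total <- total + log(p_to)
      } else {
        v <- sorted[[data$choice[j]]]
        cnt <- if (length(v))
          findInterval(data$rt[j] + eps, v) -
            findInterval(data$rt[j] - eps - 1e-12, v) else 0L
        total <- total + log(max(cnt / k, floor_p)) - log(2 * eps)
      }
    }
  }
  total
}

# Smoothed variant of the ABC kernel: identical acceptance rule, but the
# uniform non-decision time and the lapse mixture are integrated in closed
# form given the simulated crossing times, which cuts the variance of the
# likelihood estimate. Truncation of the non-decision time at 0 is ignored
# here (its mass is negligible for any plausible ndt parameters).
.kernel_loglik_smooth <- function(data, dec_by_truth, eps) {
  total <- 0
  for (g in names(dec_by_truth)) {
    d <- dec_by_truth[[g]]
    k <- length(d$dtime)
    rows <- if (g == "any") seq_len(nrow(data))
            else which(as.character(data$true_choice) == g)
    if (!length(rows)) next
    floor_p <- 0.5 / k
    lo <- d$ndt - d$ndt_spread / 2
    hi <- d$ndt + d$ndt_spread / 2
    w <- hi - lo
    crossed <- !is.na(d$dtime)
    p_to_i <- ifelse(crossed,
                     if (w > 0)
                       pmin(1, pmax(0, 1 - (d$max_rt - d$dtime - lo) / w))
                     else as.numeric(d$dtime + lo > d$max_rt),
                     1)
    p_to <- mean(p_to_i)
    pl <- d$lapse_prob
    pto <- d$timeout_lapse_prob
    a_by_choice <- lapply(1:2, function(ch)
      sort(d$dtime[crossed & d$choice == ch] + lo))
    to_rows <- rows[data$timed_out[rows]]
    if (length(to_rows))
      total <- total + length(to_rows) *
        log(max((1 - pl) * p_to + pl * pto, floor_p))
    for (ch in 1:2) {
      jj <- rows[!data$timed_out[rows] & data$choice[rows] == ch]
      if (!length(jj)) next
      wl <- pmax(data$rt[jj] - eps, 0)
      wr <- pmin(data$rt[jj] + eps, d$max_rt)
      a <- a_by_choice[[ch]]
      if (!length(a)) {
        ov <- numeric(length(jj))
      } else if (w > 0) {
        # total overlap of the sims' ndt windows [a_i, a_i + w] with the
        # trial window [wl, wr], via prefix sums of the sorted a_i:
        # rising / flat / falling regions of the piecewise-linear overlap
        pre <- c(0, cumsum(a))
        m1 <- pmin(wr - w, wl)
        m2 <- pmax(wr - w, wl)
        i0 <- findInterval(wl - w, a)
        i1 <- findInterval(m1, a)
        i2 <- findInterval(m2, a)
        i3 <- findInterval(wr, a)
        ov <- (pre[i1 + 1] - pre[i0 + 1]) + (w - wl) * (i1 - i0) +
          pmin(w, wr - wl) * (i2 - i1) +
          wr * (i3 - i2) - (pre[i3 + 1] - pre[i2 + 1])
        ov <- ov / w
      } else {
        ov <- findInterval(wr, a) - findInterval(wl - 1e-12, a)
      }
      p_acc <- ov / k
      p_lapse <- (wr - wl) / d$max_rt / 2 # uniform rt, 2 choices
      p <- (1 - pl) * p_acc + pl * (1 - pto) * p_lapse
      total <- total + sum(log(pmax(p, floor_p))) -
        length(jj) * log(2 * eps)
    }
  }
  total
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# --- importance-sampling ABC (the no-EP fallback) ---------------------------

#' Likelihood-free fit by importance-sampling ABC
#'
#' The plain (no expectation-propagation) fallback fitter. Parameter draws
#' are taken from the prior (stage 1) and then from an inflated Gaussian
#' refit (later stages, with importance correction); each draw's likelihood
#' is estimated with the ABC kernel -- a simulated response is accepted for
#' a data trial when the choice matches and the RTs differ by at most
#' `eps`; timed-out trials are matched on the timeout flag -- using a batch
#' of reference simulations shared across the (i.i.d.) trials of the
#' condition. The fitted posterior is the weighted Gaussian in transformed
#' space; the log marginal likelihood is the log mean weight of the final
#' stage.
#'
#' @param simulator A [make_model_simulator()] closure (i.i.d.-capable
#'   model).
#' @param data A [response_set()].
#' @param prior A [prior_spec()].
#' @param eps RT acceptance half-width in seconds (default 0.05).
#' @param n_particles Parameter draws per annealing stage.
#' @param n_ref Reference simulations per draw in the final stage (per
#'   alternative present in the data); warm-up stages use `n_ref_warmup`.
#' @param n_ref_warmup Reference simulations per draw while annealing.
#' @param max_stages Cap on the number of annealing stages.
#' @param inflate Proposal covariance inflation factor between stages.
#' @param ess_frac Target effective-sample-size fraction: each stage raises
#'   the tempering exponent as far as it can while keeping the effective
#'   sample size above `ess_frac * n_particles`.
#' @param prop_df Degrees of freedom of the multivariate-t proposals
#'   (heavier tails than the Gaussian fit guard the importance weights).
#' @param seed Optional integer seed.
#' @return An object of class `ebdm_posterior`: `mean`, `cov` (Gaussian fit
#'   in transformed space), `lml`, `spec`, plus the final-stage draws and
#'   normalized weights, the effective sample size `ess`, the reached
#'   tempering exponent `gamma` (1 unless `max_stages` was exhausted) and
#'   the number of stages used.
#' @export
abc_fit <- function(simulator, data, prior, eps = 0.05, n_particles = 500,
                    n_ref = 1500, n_ref_warmup = 600, max_stages = 25,
                    inflate = 1.5, ess_frac = 0.35, prop_df = 5,
                    seed = NULL) {
  stopifnot(inherits(data, "response_set"), inherits(prior, "prior_spec"),
            nrow(data) >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(prior)
  truths <- unique(data$true_choice)
  truths <- truths[!is.na(truths)]
  if (!length(truths)) truths <- 1L

  sim_dec <- attr(simulator, "sim_decisions")
  eval_loglik <- function(u, k_ref) {
    out <- numeric(nrow(u))
    for (s in seq_len(nrow(u))) {
      theta <- transform_parameters(u[s, ], prior)
      if (!is.null(sim_dec)) {
        ref <- lapply(truths, function(tr) sim_dec(theta, k_ref, tr))
        if (any(vapply(ref, is.null, logical(1)))) {
          out[s] <- -Inf
          next
        }
        names(ref) <- as.character(truths)
        out[s] <- .kernel_loglik_smooth(data, ref, eps)
      } else {
        ref <- lapply(truths, function(tr) {
          r <- simulator(theta, k_ref, true_alternative = tr)
          if (is.null(r)) return(NULL)
          r[, c("choice", "rt", "timed_out")]
        })
        if (any(vapply(ref, is.null, logical(1)))) {
          out[s] <- -Inf
          next
        }
        names(ref) <- as.character(truths)
        out[s] <- .kernel_loglik(data, ref, eps)
      }
    }
    out
  }

  lp_prior_of <- function(u)
    rowSums(stats::dnorm(u, rep(prior$mean, each = nrow(u)),
                         rep(prior$sd, each = nrow(u)), log = TRUE))

  gamma <- 0
  prop <- list(kind = "prior")
  res <- NULL
  for (stage in seq_len(max_stages)) {
    if (identical(prop$kind, "prior")) {
      u <- matrix(stats::rnorm(n_particles * p, rep(prior$mean,
                                                    each = n_particles),
                               rep(prior$sd, each = n_particles)),
                  n_particles, p)
      lp_prop <- lp_prior_of(u)
    } else {
      u <- .rmvt(n_particles, prop$mean, prop$cov, prop_df)
      lp_prop <- .dmvt_log(u, prop$mean, prop$cov, prop_df)
    }
    final_candidate <- gamma >= 1
    k_ref <- if (final_candidate) n_ref else n_ref_warmup
    loglik <- eval_loglik(u, k_ref)
    loglik[!is.finite(loglik)] <- -1e6 # invalid draws: finite so g*loglik is
    lp_prior <- lp_prior_of(u)
    base <- lp_prior - lp_prop
    ess_of <- function(g) {
      lw <- g * loglik + base
      w <- exp(lw - .logsumexp(lw))
      1 / sum(w^2)
    }
    if (!final_candidate) {
      # raise the exponent as far as possible while keeping the ESS above a
      # fraction of the stage's own noise floor (the ESS at the current
      # exponent, which reflects kernel-estimate noise), never lowering it
      ess0 <- if (gamma > 0) ess_of(gamma) else n_particles
      target <- max(25, ess_frac * ess0)
      grid <- sort(unique(pmin(1, c(gamma + 10^seq(-4, 0, 0.1), 1))))
      grid <- grid[grid > 0]
      ok <- vapply(grid, function(g) ess_of(g) >= target, logical(1))
      gamma <- if (any(ok)) max(grid[ok]) else grid[which.max(
        vapply(grid, ess_of, numeric(1)))]
    }
    logw <- gamma * loglik + base
    w <- exp(logw - .logsumexp(logw))
    m <- colSums(u * w)
    uc <- sweep(u, 2, m)
    cv <- crossprod(uc * sqrt(w), uc * sqrt(w)) + diag(1e-8, p)
    res <- structure(list(mean = stats::setNames(m, prior$param), cov = cv,
                          lml = .logsumexp(loglik + base) -
                            log(n_particles),
                          spec = prior, draws = u, weights = w,
                          ess = 1 / sum(w^2), gamma = gamma,
                          stages = stage),
                     class = "ebdm_posterior")
    if (final_candidate) break
    prop <- list(kind = "t", mean = m, cov = cv * inflate^2 +
                   diag(1e-8, p))
  }
  if (res$gamma < 1)
    warning("annealing did not reach the full likelihood within ",
            max_stages, " stages (gamma = ", signif(res$gamma, 3), ")")
  res
}

.rmvt <- function(n, mean, cov, df) {
  p <- length(mean)
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol(cov)
  g <- sqrt(df / stats::rchisq(n, df))
  sweep(z * g, 2, mean, "+")
}

.dmvt_log <- function(x, mean, cov, df) {
  p <- ncol(x)
  ch <- chol(cov)
  z <- forwardsolve(t(ch), t(sweep(x, 2, mean)))
  q <- colSums(z^2)
  lgamma((df + p) / 2) - lgamma(df / 2) - 0.5 * p * log(df * pi) -
    sum(log(diag(ch))) - 0.5 * (df + p) * log1p(q / df)
}

.dmvnorm_log <- function(x, mean, cov) {
  p <- ncol(x)
  ch <- chol(cov)
  z <- forwardsolve(t(ch), t(sweep(x, 2, mean)))
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

#' Summarize a fitted posterior in model space
#'
#' Draws from the posterior (importance weights or the Gaussian fit),
#' transforms to model space, and reports per-parameter means, sds and
#' central credible intervals.
#'
#' @param post An `ebdm_posterior` (from [abc_fit()] or [epabc_fit()]).
#' @param prob Credible-interval mass (default 0.95).
#' @param n_draws Draws used when only a Gaussian fit is available.
#' @return A data frame with columns `param`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
posterior_summary <- function(post, prob = 0.95, n_draws = 10000) {
  stopifnot(inherits(post, "ebdm_posterior"))
  a <- (1 - prob) / 2
  if (!is.null(post$draws) && !is.null(post$weights)) {
    th <- transform_parameters(post$draws, post$spec)
    w <- post$weights
    qs <- apply(th, 2, function(col) .wquantile(col, w, c(a, 1 - a)))
    mean_ <- colSums(th * w)
    sd_ <- sqrt(pmax(0, colSums(th^2 * w) - mean_^2))
  } else {
    ch <- chol(post$cov + diag(1e-10, ncol(post$cov)))
    u <- matrix(stats::rnorm(n_draws * ncol(ch)), n_draws) %*% ch
    u <- sweep(u, 2, post$mean, "+")
    th <- transform_parameters(u, post$spec)
    qs <- apply(th, 2, stats::quantile, probs = c(a, 1 - a))
    mean_ <- colMeans(th)
    sd_ <- apply(th, 2, stats::sd)
  }
  data.frame(param = post$spec$param, mean = mean_, sd = sd_,
             lower = qs[1, ], upper = qs[2, ], row.names = NULL)
}

.wquantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which.max(cw >= p)], numeric(1))
}

#' @export
print.ebdm_posterior <- function(x, ...) {
  cat("ebdm_posterior over", nrow(x$spec), "parameters; log marginal",
      "likelihood", signif(x$lml, 6), "\n")
  print(posterior_summary(x))
  invisible(x)
}

# --- EP-ABC -----------------------------------------------------------------

.gauss_logpart <- function(h, K) {
  p <- length(h)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  m <- backsolve(ch, forwardsolve(t(ch), h))
  0.5 * sum(h * m) - sum(log(diag(ch))) + 0.5 * p * log(2 * pi)
}

#' Likelihood-free fit by EP-ABC
#'
#' Expectation-propagation ABC: one Gaussian site per trial (in transformed
#' parameter space), updated by sampling from the site's cavity
#' distribution, simulating one response per draw for that trial, and
#' moment-matching the accepted draws (same acceptance kernel as
#' [abc_fit()]). Updates are damped by `alpha`, the matched covariance
#' diagonal is floored at `veps` times the cavity diagonal, updates that
#' would break positive definiteness are rejected, and the data are passed
#' through `passes` times. Returns the Gaussian posterior and an EP
#' estimate of the log marginal likelihood assembled from the site
#' normalizers.
#'
#' @param simulator A [make_model_simulator()] closure.
#' @param data A [response_set()].
#' @param prior A [prior_spec()].
#' @param eps RT acceptance half-width (seconds).
#' @param min_accept Minimum accepted draws per site update.
#' @param max_samples_per_trial Sampling budget per site update.
#' @param alpha Damping factor in (0, 1].
#' @param veps Relative variance floor for site updates.
#' @param passes Number of passes through the trials.
#' @param batch Draws per simulation batch.
#' @param stimuli Optional `dot_stimuli` aligned with `data` rows (for
#'   exact-input models).
#' @param seed Optional integer seed.
#' @param verbose Print per-pass progress?
#' @return An `ebdm_posterior` with fields `mean`, `cov`, `lml`, `spec`,
#'   and `flagged` (trials whose update fell short of `min_accept`).
#' @export
epabc_fit <- function(simulator, data, prior, eps = 0.05,
                      min_accept = 2000, max_samples_per_trial = 6e6,
                      alpha = 0.5, veps = 0.2, passes = 2, batch = 5000,
                      stimuli = NULL, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "response_set"), inherits(prior, "prior_spec"))
  if (!is.null(seed)) set.seed(seed)
  sim_one <- attr(simulator, "sim_one")
  p <- nrow(prior)
  n <- nrow(data)
  K0 <- diag(1 / prior$sd^2, p)
  h0 <- prior$mean / prior$sd^2
  Q <- replicate(n, matrix(0, p, p), simplify = FALSE)
  r <- replicate(n, numeric(p), simplify = FALSE)
  cs <- numeric(n) # site log-constants
  Kg <- K0
  hg <- h0
  flagged <- integer(0)

  match_trial <- function(sim, j) {
    if (data$timed_out[j]) sim$valid & sim$timed_out
    else sim$valid & !sim$timed_out & sim$choice == data$choice[j] &
      abs(sim$rt - data$rt[j]) <= eps
  }

  for (pass in seq_len(passes)) {
    for (j in seq_len(n)) {
      Kc <- Kg - Q[[j]]
      hc <- hg - r[[j]]
      chc <- tryCatch(chol(Kc), error = function(e) NULL)
      if (is.null(chc)) next
      Sc <- chol2inv(chc)
      mc <- Sc %*% hc
      csc <- chol(Sc)
      acc_u <- matrix(numeric(0), 0, p)
      n_sim <- 0L
      while (nrow(acc_u) < min_accept && n_sim < max_samples_per_trial) {
        b <- min(batch, max_samples_per_trial - n_sim)
        u <- matrix(stats::rnorm(b * p), b, p) %*% csc
        u <- sweep(u, 2, as.numeric(mc), "+")
        colnames(u) <- prior$param
        th <- transform_parameters(u, prior)
        truth_j <- if (is.na(data$true_choice[j])) 1L
                   else data$true_choice[j]
        sim <- sim_one(th, truth = truth_j,
                       stimulus_row = if (!is.null(stimuli))
                         stimuli$frames[j, ] else NULL)
        ok <- match_trial(sim, j)
        n_sim <- n_sim + b
        if (any(ok)) acc_u <- rbind(acc_u, u[ok, , drop = FALSE])
      }
      n_acc <- nrow(acc_u)
      if (n_acc < max(p + 2, min(min_accept, 20))) {
        flagged <- union(flagged, j)
        next
      }
      damp <- if (n_acc < min_accept) alpha / 2 else alpha
      m_hat <- colMeans(acc_u)
      S_hat <- stats::cov(acc_u)
      d <- diag(S_hat)
      floor_d <- veps * diag(Sc)
      if (any(d < floor_d))
        diag(S_hat) <- pmax(d, floor_d)
      Kn <- tryCatch(chol2inv(chol(S_hat)), error = function(e) NULL)
      if (is.null(Kn)) {
        flagged <- union(flagged, j)
        next
      }
      hn <- Kn %*% m_hat
      Qj_new <- (1 - damp) * Q[[j]] + damp * (Kn - Kc)
      rj_new <- (1 - damp) * r[[j]] + damp * (as.numeric(hn) - hc)
      Kg_new <- Kc + Qj_new
      hg_new <- hc + rj_new
      if (is.na(.gauss_logpart(hg_new, Kg_new))) {
        flagged <- union(flagged, j)
        next
      }
      log_zhat <- log(n_acc / n_sim) -
        (if (data$timed_out[j]) 0 else log(2 * eps))
      cs[j] <- log_zhat + .gauss_logpart(hc, Kc) -
        .gauss_logpart(hg_new, Kg_new)
      Q[[j]] <- Qj_new
      r[[j]] <- rj_new
      Kg <- Kg_new
      hg <- hg_new
    }
    if (verbose)
      message("pass ", pass, ": ", length(flagged), " flagged trials")
  }
  Sg <- chol2inv(chol(Kg))
  mg <- as.numeric(Sg %*% hg)
  lml <- sum(cs) + .gauss_logpart(hg, Kg) - .gauss_logpart(h0, K0)
  structure(list(mean = stats::setNames(mg, prior$param), cov = Sg,
                 lml = lml, spec = prior, draws = NULL, weights = NULL,
                 flagged = flagged),
            class = "ebdm_posterior")
}
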