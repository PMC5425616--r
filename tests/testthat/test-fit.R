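# Likelihood-free fitting: transformations, ABC kernel, the two fitters.

test_that("parameter transformations and their inverses", {
  spec <- prior_spec(param = c("a", "b", "c"),
                     kind = c("exp", "unif", "none"),
                     mean = c(0, 0, 1), sd = c(1, 1, 2),
                     lower = 0.2, upper = 0.8)
  th <- transform_parameters(c(0, 0, 3), spec)
  expect_equal(unname(th), c(1, 0.5, 3)) # e^0; interval midpoint; identity
  set.seed(1)
  u <- matrix(rnorm(30), 10, 3)
  back <- inverse_transform_parameters(transform_parameters(u, spec), spec)
  expect_lt(max(abs(back - u)), 1e-10)
})

test_that("default priors encode the documented table", {
  pr <- default_priors("ebm")
  expect_equal(nrow(pr), 9)
  expect_equal(pr$kind[pr$param == "mean_noise"], "exp")
  expect_equal(pr$mean[pr$param == "mean_noise"], 5)
  expect_equal(pr$mean[pr$param == "noise_var"], -10)
  expect_equal(pr$sd[pr$param == "noise_var"], 3)
  expect_equal(pr$kind[pr$param == "bound"], "unif")
  expect_equal(pr$mean[pr$param == "prior_spread"], -2)
  pr_bm <- default_priors("bm")
  expect_false(any(c("noise_var", "prior_spread") %in% pr_bm$param))
})

test_that("the ABC kernel counts what it should", {
  ref <- data.frame(choice = c(1, 1, 1, 2, NA),
                    rt = c(0.50, 0.52, 0.60, 0.55, 5),
                    timed_out = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  data <- response_set(choice = c(1, 2, NA), rt = c(0.51, 0.56, 5),
                       timed_out = c(FALSE, FALSE, TRUE), true_choice = 1)
  eps <- 0.05
  ll <- ebdm:::.kernel_loglik(data, list(`1` = ref), eps)
  # trial 1: two sims within [0.46, 0.56] with choice 1 -> 2/5 / (2 eps)
  # trial 2: one sim with choice 2 within window  -> 1/5 / (2 eps)
  # trial 3: one timeout -> 1/5
  expect_equal(ll, log(2 / 5 / 0.1) + log(1 / 5 / 0.1) + log(1 / 5))
})

test_that("smoothed kernel agrees with the sampled kernel in expectation", {
  gen <- sweep_world_bm()
  sim <- make_model_simulator("bm", fixed = list(ndt_spread = 0.2,
                                                 mean_prior = 0.5))
  data <- simulate_ebm(sweep_world_ebm(), 60, seed = 2)
  theta <- c(bound = 0.8, mean_noise = 222.5538, ndt = 0.4)
  set.seed(3)
  d1 <- attr(sim, "sim_decisions")(theta, 4000, 1)
  d2 <- attr(sim, "sim_decisions")(theta, 4000, 2)
  ll_smooth <- ebdm:::.kernel_loglik_smooth(data, list(`1` = d1, `2` = d2),
                                            0.05)
  set.seed(3)
  r1 <- sim(theta, 4000, true_alternative = 1)
  r2 <- sim(theta, 4000, true_alternative = 2)
  ll_samp <- ebdm:::.kernel_loglik(
    data, list(`1` = r1[, c("choice", "rt", "timed_out")],
               `2` = r2[, c("choice", "rt", "timed_out")]), 0.05)
  expect_lt(abs(ll_smooth - ll_samp), 4 * sqrt(60) * 0.2)
})

test_that("simulator factory rejects invalid parameter regions", {
  sim <- make_model_simulator("bm")
  expect_null(sim(c(bound = 0.4, mean_noise = 100, ndt = 0.3), 10))
  expect_null(sim(c(bound = 0.8, mean_noise = -5, ndt = 0.3), 10))
  r <- sim(c(bound = 0.8, mean_noise = 100, ndt = 0.3), 10)
  expect_s3_class(r, "response_set")
})

test_that("abc_fit recovers generating parameters on synthetic data", {
  gen <- sweep_world_ebm()
  sim <- make_model_simulator("bm", fixed = list(ndt_spread = 0.2,
                                                 mean_prior = 0.5))
  prior <- default_priors("bm", free = c("bound", "mean_noise", "ndt"))
  data <- simulate_ebm(gen, 200, seed = 4)
  post <- abc_fit(sim, data, prior, n_particles = 300, n_ref = 800,
                  n_ref_warmup = 400, seed = 5)
  expect_equal(post$gamma, 1)
  s <- posterior_summary(post)
  expect_lt(abs(s$mean[s$param == "bound"] - 0.8), 0.08)
  expect_lt(abs(s$mean[s$param == "mean_noise"] - 222.5538), 70)
  expect_lt(abs(s$mean[s$param == "ndt"] - 0.4), 0.06)
  expect_true(all(is.finite(post$lml)))
})

test_that("wrong-sign input is dominated in marginal likelihood", {
  sim_ok <- make_model_simulator("bm", fixed = list(ndt_spread = 0.2,
                                                    mean_prior = 0.5))
  # mis-specified observer: input features point at the wrong alternative
  # relative to the generative models
  sim_bad <- make_model_simulator("bm",
                                  fixed = list(ndt_spread = 0.2,
                                               mean_prior = 0.5),
                                  feature_means = c(-25, 25),
                                  gen_means = c(25, -25))
  prior <- default_priors("bm", free = c("bound", "mean_noise", "ndt"))
  data <- simulate_ebm(sweep_world_ebm(), 120, seed = 6,
                       true_alternative = 1)
  p_ok <- abc_fit(sim_ok, data, prior, n_particles = 250, n_ref = 600,
                  n_ref_warmup = 300, seed = 7)
  p_bad <- suppressWarnings( # dominated model: capped annealing intended
    abc_fit(sim_bad, data, prior, n_particles = 250, n_ref = 600,
            n_ref_warmup = 300, max_stages = 10, seed = 8))
  expect_gt(p_ok$lml - p_bad$lml, 20)
})

test_that("variability parameters stay prior-wide on BM-generated data", {
  # data without inter-trial variability carry little information about
  # noise_var / prior_spread: their posterior sd stays a sizable fraction
  # of the prior sd
  sim <- make_model_simulator("ebm", fixed = list(ndt_spread = 0.2,
                                                  mean_prior = 0.5,
                                                  bound = 0.8, ndt = 0.4,
                                                  mean_noise = 222.5538))
  prior <- default_priors("ebm", free = c("noise_var", "prior_spread"))
  data <- simulate_ebm(sweep_world_ebm(), 150, seed = 9)
  post <- abc_fit(sim, data, prior, n_particles = 250, n_ref = 500,
                  n_ref_warmup = 300, max_stages = 12, seed = 10)
  sd_post <- sqrt(diag(post$cov))
  expect_gt(sd_post[1] / prior$sd[prior$param == "noise_var"], 0.4)
  expect_gt(sd_post[2] / prior$sd[prior$param == "prior_spread"], 0.4)
})

test_that("posterior contracts when the data double", {
  sim <- make_model_simulator("bm", fixed = list(ndt_spread = 0.2,
                                                 mean_prior = 0.5,
                                                 ndt = 0.4))
  prior <- default_priors("bm", free = c("bound", "mean_noise"))
  d1 <- simulate_ebm(sweep_world_ebm(), 100, seed = 11)
  d2 <- simulate_ebm(sweep_world_ebm(), 400, seed = 12)
  p1 <- abc_fit(sim, d1, prior, n_particles = 250, n_ref = 600,
                n_ref_warmup = 300, seed = 13)
  # the 400-trial likelihood is sharper and its kernel estimate noisier:
  # larger reference batches keep the annealing noise floor low enough to
  # reach the full likelihood
  p2 <- abc_fit(sim, d2, prior, n_particles = 250, n_ref = 1000,
                n_ref_warmup = 600, max_stages = 40, seed = 14)
  expect_lt(sqrt(diag(p2$cov))[1], sqrt(diag(p1$cov))[1])
  expect_lt(sqrt(diag(p2$cov))[2], sqrt(diag(p1$cov))[2])
})

test_that("epabc_fit approximates the same posterior", {
  gen <- sweep_world_ebm()
  sim <- make_model_simulator("bm", fixed = list(ndt_spread = 0.2,
                                                 mean_prior = 0.5,
                                                 mean_noise = 222.5538))
  prior <- default_priors("bm", free = c("bound", "ndt"))
  data <- simulate_ebm(gen, 60, seed = 15)
  post <- epabc_fit(sim, data, prior, min_accept = 300,
                    max_samples_per_trial = 60000, passes = 2, seed = 16)
  s <- posterior_summary(post)
  expect_lt(abs(s$mean[s$param == "bound"] - 0.8), 0.1)
  expect_lt(abs(s$mean[s$param == "ndt"] - 0.4), 0.08)
  expect_true(is.finite(post$lml))
  expect_true(all(eigen(post$cov, only.values = TRUE)$values > 0))
})

test_that("marginal-likelihood ordering is stable under reparameterization", {
  # the BM simulator and the same model fed through translated pDDM
  # parameters define the same response distribution; their evidence gap is
  # small next to the gap to a dominated (wrong-sign) model
  prior <- default_priors("bm", free = c("bound", "mean_noise", "ndt"))
  data <- simulate_ebm(sweep_world_ebm(), 100, seed = 17)
  sim_a <- make_model_simulator("bm", fixed = list(ndt_spread = 0.2,
                                                   mean_prior = 0.5))
  # same model on a rescaled feature axis (+/-50): the noise level doubles
  # but the response distribution is identical at matched parameters
  sim_b <- make_model_simulator("bm", fixed = list(ndt_spread = 0.2,
                                                   mean_prior = 0.5),
                                feature_means = c(50, -50), dt = 0.05)
  sim_bad <- make_model_simulator("bm",
                                  fixed = list(ndt_spread = 0.2,
                                               mean_prior = 0.5),
                                  feature_means = c(-25, 25),
                                  gen_means = c(25, -25))
  la <- abc_fit(sim_a, data, prior, n_particles = 250, n_ref = 600,
                n_ref_warmup = 300, seed = 18)$lml
  lb <- abc_fit(sim_b, data, prior, n_particles = 250, n_ref = 600,
                n_ref_warmup = 300, seed = 19)$lml
  lbad <- suppressWarnings(
    abc_fit(sim_bad, data, prior, n_particles = 250, n_ref = 600,
            n_ref_warmup = 300, max_stages = 10, seed = 20))$lml
  # the scale change costs at most a few units (prior shift + estimator
  # noise); the mis-specified model loses tens
  expect_lt(abs(la - lb), max(4, 0.3 * (la - lbad)))
})
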