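# BM core: uncertainty coupling, input process, likelihoods, posterior
# recursion, bound policy, lapses.

test_that("internal uncertainty coupling and its scaling", {
  expect_equal(internal_uncertainty_from_noise(1, 1, 1, -1, 1)^2, 2)
  # linear in the noise level
  s1 <- internal_uncertainty_from_noise(100, 2.8, 25, -25, 0.05)^2
  s2 <- internal_uncertainty_from_noise(200, 2.8, 25, -25, 0.05)^2
  expect_equal(s2 / s1, 2)
  # sweep-world value: sigma * |mu1 - mu2| / (dt * s)
  expect_equal(internal_uncertainty_from_noise(222.5538, 2.8, 25, -25,
                                               0.05)^2,
               222.5538 * 50 / (0.05 * 2.8))
  expect_error(internal_uncertainty_from_noise(1, 1, 3, 3, 1), "degenerate")
})

test_that("sampled input sequences have the stated moments", {
  x0 <- sample_input_sequence(25, 0, 0.05, 10, 1)
  expect_true(all(x0$features == 25))
  set.seed(5)
  x <- sample_input_sequence(2, 30, 0.05, 2e5)
  expect_lt(abs(mean(x$features) - 2), 4 * 30 * sqrt(0.05) / sqrt(2e5))
  v <- stats::var(x$features)
  expect_lt(abs(v - 0.05 * 900), 4 * 0.05 * 900 * sqrt(2 / 2e5))
  set.seed(6)
  a <- sample_input_sequence(2, 30, 0.05, 100)
  set.seed(6)
  b <- sample_input_sequence(2, 30, 0.05, 100)
  expect_identical(a, b)
})

test_that("log likelihoods: mode, symmetry and the linear log-odds slope", {
  ll <- log_likelihoods(1, c(1, -1), 2, 0.1)
  expect_gt(ll[1], ll[2])
  expect_equal(diff(log_likelihoods(0, c(1, -1), 2, 0.1)), 0)
  # two-alternative log-likelihood difference is linear in x with slope
  # (mu1 - mu2) / (dt * sigma_hat^2) -- the DDM-equivalence mechanism
  sl <- (1 - (-1)) / (0.1 * 4)
  d <- function(x) diff(rev(log_likelihoods(x, c(1, -1), 2, 0.1)))
  xs <- c(-2, -0.5, 0.3, 1.7)
  expect_equal(vapply(xs, d, numeric(1)), sl * xs)
})

test_that("posterior updates: identities and normalization", {
  expect_equal(update_posterior(c(0.3, 0.7), c(-1, -1)), c(0.3, 0.7))
  expect_equal(update_posterior(c(1, 0), c(-50, 0)), c(1, 0))
  # sequential updates equal one batch update with summed log likelihoods
  set.seed(7)
  ll <- matrix(rnorm(30), 10, 3)
  p_seq <- c(0.2, 0.5, 0.3)
  for (k in 1:10) p_seq <- update_posterior(p_seq, ll[k, ])
  lp <- log(c(0.2, 0.5, 0.3)) + colSums(ll)
  p_batch <- exp(lp - max(lp)) / sum(exp(lp - max(lp)))
  expect_equal(p_seq, p_batch, tolerance = 1e-12)
  expect_equal(sum(p_seq), 1, tolerance = 1e-12)
})

test_that("run_bm_trial crosses when the log-odds walk says so", {
  b <- sweep_world_bm()
  set.seed(8)
  inp <- sample_input_sequence(25, b$noise, b$dt, 100, 1)
  set.seed(9)
  out <- run_bm_trial(b, inp)
  # reference: cumulative log-odds of the same input stream
  a <- (b$gen_means[1] - b$gen_means[2]) / (b$dt * b$uncertainty^2)
  L <- qlogis(b$prior) + cumsum(a * inp$features)
  k_ref <- which(abs(L) >= qlogis(b$bound))[1]
  expect_identical(out$trace$decision_step, as.integer(k_ref))
  expect_identical(out$choice, if (L[k_ref] > 0) 1L else 2L)
  # posterior rows normalized
  expect_true(all(abs(rowSums(out$trace$posteriors) - 1) < 1e-12))
  expect_true(all(out$trace$posteriors >= 0 &
                  out$trace$posteriors <= 1))
})

test_that("noiseless input at the first alternative's mean always picks it", {
  b <- bm_params(bound = 0.8, noise = 100, prior = 0.5,
                 feature_means = c(25, -25), dt = 0.05, ndt = 0)
  inp <- input_sequence(rep(25, 50), 0.05, 1)
  out <- run_bm_trial(b, inp)
  expect_identical(out$choice, 1L)
})

test_that("bm_params rejects a prior at or above the bound", {
  expect_error(bm_params(bound = 0.6, noise = 10, prior = 0.7), "prior")
  expect_error(bm_params(bound = 0.6, noise = 10, prior = 0.3), "prior")
})

test_that("lapse model: identity, saturation and the joint timeout rate", {
  r <- simulate_bm(sweep_world_bm(), 2000, seed = 10)
  set.seed(11)
  expect_identical(apply_lapse(r, 0, 0.5, 5), r)
  set.seed(12)
  all_to <- apply_lapse(r, 1, 1, 5)
  expect_true(all(all_to$timed_out))
  set.seed(13)
  half <- apply_lapse(simulate_bm(sweep_world_bm(), 1e5, seed = 14),
                      0.5, 0.5, 5)
  expect_prop_close(mean(half$timed_out), 0.25, 1e5)
})

test_that("posterior log-odds increments match the translated DDM walk", {
  # regression of simulated increments: mean = v*dt, sd = s*sqrt(dt)
  b <- sweep_world_bm()
  a <- (b$gen_means[1] - b$gen_means[2]) / (b$dt * b$uncertainty^2)
  set.seed(15)
  x <- rnorm(2e5, 25, sqrt(b$dt) * b$noise)
  inc <- a * x
  v_equiv <- b$diffusion_scale * 25 / (b$dt * b$noise)
  expect_lt(abs(mean(inc) - v_equiv * b$dt),
            4 * sd(inc) / sqrt(2e5))
  expect_lt(abs(sd(inc) - b$diffusion_scale * sqrt(b$dt)), 0.01)
})

test_that("lowering the bound stochastically speeds decisions", {
  hi <- simulate_bm(sweep_world_bm(), 20000, seed = 16)
  lo_p <- bm_params(bound = 0.7, noise = 222.5538, ndt = 0.4,
                    ndt_spread = 0.2, feature_means = c(25, -25))
  lo <- simulate_bm(lo_p, 20000, seed = 16)
  q <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  expect_true(all(quantile(lo$rt[!lo$timed_out], q) <=
                  quantile(hi$rt[!hi$timed_out], q) + 1e-9))
})
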