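# Pure and extended drift-diffusion simulators.

test_that("parameter constructors enforce their domains", {
  expect_error(pddm_params(drift = 1, boundary = -1), "boundary")
  expect_error(pddm_params(drift = 1, boundary = 1, bias = 1), "bias")
  expect_error(pddm_params(drift = 1, boundary = 1, dt = 0), "dt")
  expect_error(eddm_params(mean_drift = 1, boundary = 1, mean_bias = 0.9,
                           bias_spread = 0.4), "bias support")
  expect_error(eddm_params(mean_drift = 1, boundary = 1, mean_ndt = 0.1,
                           ndt_spread = 0.4), "ndt")
  expect_silent(eddm_params(mean_drift = 1, boundary = 1))
})

test_that("pddm trial: symmetric no-drift process picks each bound equally", {
  p <- pddm_params(drift = 0, boundary = 1, bias = 0, ndt = 0.3,
                   diffusion = 1, dt = 0.01)
  r <- simulate_pddm(p, 20000, max_time = 20, seed = 1)
  expect_prop_close(mean(r$choice[!r$timed_out] == 1), 0.5,
                    sum(!r$timed_out))
})

test_that("pddm trial: boundary-adjacent start crosses immediately", {
  p <- pddm_params(drift = 5, boundary = 1, bias = 1 - 1e-9, ndt = 0,
                   diffusion = 1, dt = 0.01)
  set.seed(2)
  out <- replicate(200, {
    tr <- simulate_pddm_trial(p, max_time = 1)
    c(tr$choice, tr$trace$crossing_step)
  })
  expect_gt(mean(out[1, ] == 1), 0.9)
  # P(first step up) ~ pnorm(drift*dt / (sqrt(dt)*s)) ~ 0.69
  expect_gt(mean(out[2, ] == 1), 0.55)
})

test_that("pddm upper-bound probability matches the Wiener closed form", {
  # small dt so discretization bias is below Monte-Carlo error
  cases <- list(c(v = 1, B = 1, z = 0), c(v = 2, B = 1.4, z = 0),
                c(v = 1.5, B = 1, z = 0.4))
  for (cs in cases) {
    p <- pddm_params(drift = cs["v"], boundary = cs["B"], bias = cs["z"],
                     ndt = 0, diffusion = 1, dt = 0.001)
    r <- simulate_pddm(p, 20000, max_time = 30, seed = 7)
    expect_lt(mean(r$timed_out), 0.001)
    p_up <- wiener_upper_prob(cs["v"], 1, cs["B"], cs["z"])
    expect_prop_close(mean(r$choice[!r$timed_out] == 1), p_up, 20000)
  }
})

test_that("eddm trial-parameter sampling has the stated distributions", {
  ext <- eddm_params(mean_drift = 1.5, drift_sd = 0.4, boundary = 1.4,
                     mean_bias = 0.2, bias_spread = 0.5, mean_ndt = 0.4,
                     ndt_spread = 0.2)
  # zero spreads return the means exactly
  ext0 <- eddm_params(mean_drift = 1.5, boundary = 1.4, mean_bias = 0.2,
                      mean_ndt = 0.4)
  p0 <- sample_eddm_trial_params(ext0)
  expect_identical(c(p0$drift, p0$bias, p0$ndt), c(1.5, 0.2, 0.4))

  set.seed(11)
  draws <- replicate(5000, {
    p <- sample_eddm_trial_params(ext)
    c(p$drift, p$bias, p$ndt)
  })
  expect_lt(abs(mean(draws[1, ]) - 1.5), 4 * 0.4 / sqrt(5000))
  expect_true(all(draws[2, ] >= 0.2 - 0.25 & draws[2, ] <= 0.2 + 0.25))
  expect_true(all(draws[3, ] >= 0.3 & draws[3, ] <= 0.5))
})

test_that("eddm reduces to pddm with zero spreads and is seed-stable", {
  ext <- eddm_params(mean_drift = 2, boundary = 1.4, mean_ndt = 0.3,
                     diffusion = 2.8)
  p <- pddm_params(drift = 2, boundary = 1.4, ndt = 0.3, diffusion = 2.8)
  re <- simulate_eddm(ext, 50000, seed = 5)
  rp <- simulate_pddm(p, 50000, seed = 6)
  q <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  expect_lt(max(abs(quantile(re$rt[!re$timed_out], q) -
                    quantile(rp$rt[!rp$timed_out], q))), 0.05 + 1e-9)
  expect_prop_close(mean(re$choice[!re$timed_out] == 1),
                    mean(rp$choice[!rp$timed_out] == 1), 50000)
  expect_identical(simulate_eddm(ext, 100, seed = 9),
                   simulate_eddm(ext, 100, seed = 9))
})

test_that("drift variability slows errors; bias variability speeds them", {
  slow <- eddm_params(mean_drift = 2, drift_sd = 1.8, boundary = 1.4,
                      mean_ndt = 0.4, ndt_spread = 0.2)
  rs <- simulate_eddm(slow, 50000, seed = 21)
  s <- summarize_responses(rs)
  expect_gt(s$median_rt_error, s$median_rt_correct)

  fast <- eddm_params(mean_drift = 2, drift_sd = 0, boundary = 1.4,
                      bias_spread = 2.2, mean_ndt = 0.4, ndt_spread = 0.2)
  rf <- simulate_eddm(fast, 50000, seed = 22)
  f <- summarize_responses(rf)
  expect_lt(f$median_rt_error, f$median_rt_correct)
})

test_that("rt of decided trials is at least the trial's ndt sample", {
  ext <- eddm_params(mean_drift = 2, boundary = 1.4, mean_ndt = 0.4,
                     ndt_spread = 0.2)
  r <- simulate_eddm(ext, 5000, seed = 31)
  expect_true(all(r$rt[!r$timed_out] >= 0.3 + ext$dt - 1e-9))
})

test_that("accuracy is non-decreasing in drift on a drift grid", {
  accs <- vapply(c(0.5, 1, 2, 4, 8), function(v) {
    r <- simulate_pddm(pddm_params(drift = v, boundary = 1.4, ndt = 0.3),
                       20000, seed = 41)
    mean(r$choice[!r$timed_out] == 1)
  }, numeric(1))
  expect_true(all(diff(accs) > -0.01)) # monotone up to Monte-Carlo jitter
})
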