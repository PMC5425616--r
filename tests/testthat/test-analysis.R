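# Summaries, sweeps, QP and QQ tables.

test_that("summaries handle the simple cases and exclude timeouts", {
  r <- response_set(choice = c(1, 1, 1, NA), rt = c(0.5, 0.5, 0.5, 5),
                    timed_out = c(FALSE, FALSE, FALSE, TRUE),
                    true_choice = 1)
  s <- summarize_responses(r)
  expect_equal(s$proportion_correct, 1)
  expect_equal(s$median_rt, 0.5)
  expect_equal(s$timeout_fraction, 0.25)
  expect_true(is.na(s$median_rt_error))
  expect_error(summarize_responses(
    response_set(choice = NA_integer_, rt = 5, timed_out = TRUE,
                 true_choice = 1)), "no decided")
})

test_that("symmetric no-drift simulation summarizes to chance accuracy", {
  p <- pddm_params(drift = 0, boundary = 1, ndt = 0.3, diffusion = 2.8,
                   dt = 0.05)
  r <- simulate_pddm(p, 20000, max_time = 10, seed = 1)
  expect_prop_close(summarize_responses(r)$proportion_correct, 0.5,
                    sum(!r$timed_out))
})

test_that("summary of a fixed-seed run is bit-reproducible", {
  e <- sweep_world_ebm(noise_var = 0.001, prior_spread = 0.1)
  s1 <- summarize_responses(simulate_ebm(e, 20000, seed = 2))
  s2 <- summarize_responses(simulate_ebm(e, 20000, seed = 2))
  expect_identical(s1, s2)
})

test_that("task-difficulty sweep shows the difficulty gradient", {
  s <- sweep_task_difficulty(n_grid = c(5, 4), n_trials = 3000, seed = 3)
  expect_equal(nrow(s), 20)
  # increasing mean noise at fixed variability lowers accuracy, raises RT
  for (eta in unique(s$noise_var)) {
    sub <- s[s$noise_var == eta, ]
    sub <- sub[order(sub$mean_noise), ]
    expect_lt(sub$proportion_correct[5], sub$proportion_correct[1])
    expect_gt(sub$median_rt[5], sub$median_rt[1])
  }
  # cells carry their seed and are reproducible
  s2 <- sweep_task_difficulty(n_grid = c(5, 4), n_trials = 3000, seed = 3)
  expect_identical(s, s2)
})

test_that("error-speed sweep has the slow/fast corner structure", {
  s <- sweep_error_speed(n_grid = c(4, 4), n_trials = 20000, seed = 4)
  # large prior spread & small noise variability -> fast errors (positive)
  expect_gt(s$rt_diff[s$noise_var == min(s$noise_var) &
                      s$prior_spread == max(s$prior_spread)], 0)
  # large noise variability -> slow errors (negative) for all spreads
  expect_true(all(s$rt_diff[s$noise_var == max(s$noise_var)] < 0))
  # no variability -> no RT difference
  base <- simulate_ebm(sweep_world_ebm(), 1e5, seed = 5)
  sb <- summarize_responses(base)
  expect_lt(abs(sb$median_rt_correct - sb$median_rt_error), 0.015)
})

test_that("quantile-probability table has the documented structure", {
  sums <- lapply(c(168, 564), function(sg)
    summarize_responses(simulate_ebm(sweep_world_ebm(
      mean_noise = sg, noise_var = 5e-4, prior_spread = 0.2), 20000,
      seed = 6)))
  qp <- quantile_probability_data(sums, labels = c("easy", "hard"))
  expect_equal(nrow(qp), 2 * 2 * 5)
  # correct and error probabilities sum to one per condition
  agg <- tapply(qp$response_prob, list(qp$condition, qp$type), unique)
  expect_equal(unname(agg[, "correct"] + agg[, "error"]), c(1, 1))
  # quantile lines monotone within condition and type
  for (cond in unique(qp$condition))
    for (ty in unique(qp$type)) {
      rt <- qp$rt[qp$condition == cond & qp$type == ty]
      expect_true(all(diff(rt) >= 0))
    }
  # harder condition (larger noise) is slower and less accurate
  expect_gt(sums[[2]]$median_rt, sums[[1]]$median_rt)
  expect_lt(sums[[2]]$proportion_correct, sums[[1]]$proportion_correct)
})

test_that("qq percentiles: diagonal identity, caps, error-speed direction", {
  x <- seq(0.3, 1.1, length.out = 300)
  qq <- qq_percentiles(x, x)
  expect_equal(qq$rt_correct, qq$rt_error)
  expect_lte(nrow(qq), 100)
  expect_true(all(qq$rt_correct <= 1.2))
  slow <- simulate_ebm(sweep_world_ebm(noise_var = 0.001,
                                       prior_spread = 0.014), 50000,
                       seed = 7)
  ok <- !slow$timed_out
  correct <- slow$choice == slow$true_choice
  qs <- qq_percentiles(slow$rt[ok & correct], slow$rt[ok & !correct])
  # slow errors: error percentiles above the diagonal in the upper half
  upper <- qs$percentile > 50
  expect_gt(mean(qs$rt_error[upper] > qs$rt_correct[upper]), 0.8)
})
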