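# Exact equivalence maps, change-of-variables densities, approximation fit.

ctx25 <- translation_context(25)           # sweep-world scale (s = 2.8)
ctx1 <- translation_context(1, diffusion = 0.1) # classical DDM scale

test_that("logistic translations and their limits", {
  p <- pddm_params(drift = 2, boundary = 1e-9, bias = 0, ndt = 0.3)
  expect_equal(pddm_to_bm(p, ctx25)$bound, 0.5, tolerance = 1e-8)
  p2 <- pddm_params(drift = 2, boundary = 2, bias = 1.999, ndt = 0.3)
  expect_gt(pddm_to_bm(p2, ctx25)$prior, 0.87)
  b <- bm_params(bound = 0.8, noise = 100, feature_means = c(25, -25))
  expect_equal(bm_to_pddm(b, ctx25)$boundary, log(4))
  expect_error(pddm_to_bm(pddm_params(drift = 0, boundary = 1), ctx25),
               "drift")
})

test_that("round trip pddm -> bm -> pddm recovers parameters to 1e-10", {
  set.seed(1)
  for (i in 1:20) {
    p <- pddm_params(drift = runif(1, 0.2, 6), boundary = runif(1, 0.5, 3),
                     bias = runif(1, -0.4, 0.4), ndt = runif(1, 0.1, 0.5))
    b <- pddm_to_bm(p, ctx25)
    p2 <- bm_to_pddm(b, ctx25)
    expect_lt(abs(p2$drift - p$drift), 1e-10)
    expect_lt(abs(p2$boundary - p$boundary), 1e-10)
    expect_lt(abs(p2$bias - p$bias), 1e-10)
    expect_true(b$bound > 0 && b$bound < 1 && b$prior > 0 && b$prior < 1)
  }
})

test_that("exact prior density: normalization, symmetry, histogram match", {
  z_bar <- 0
  s_z <- 0.08
  f <- function(p) prior_density_exact(p, z_bar, s_z)
  lo <- plogis(z_bar - s_z / 2)
  hi <- plogis(z_bar + s_z / 2)
  expect_lt(abs(integrate(f, lo, hi, abs.tol = 1e-10)$value - 1), 1e-6)
  expect_equal(f(0.5 - 0.005), f(0.5 + 0.005))
  # logistic-transformed uniform bias samples follow the density (KS)
  set.seed(2)
  p0 <- plogis(runif(2e5, z_bar - s_z / 2, z_bar + s_z / 2))
  ks <- max(abs(seq_along(p0) / 2e5 -
                prior_cdf_exact(sort(p0), z_bar, s_z)))
  expect_lt(ks, 1.63 / sqrt(2e5)) # 1% critical value
})

test_that("exact noise density: mass on both branches, flipped mass", {
  nu <- 0.133
  eta <- 0.12
  f <- function(s) noise_density_exact(s, nu, eta, ctx1)
  pos <- integrate(f, 0, Inf, abs.tol = 1e-10, rel.tol = 1e-10)$value
  neg <- integrate(f, -Inf, 0, abs.tol = 1e-10, rel.tol = 1e-10)$value
  expect_lt(abs(pos + neg - 1), 1e-6)
  expect_lt(abs(neg - negative_drift_prob(nu, eta)), 1e-6)
  # histogram of c/v over Gaussian drift samples matches the density (KS
  # against the closed-form CDF)
  set.seed(3)
  v <- rnorm(2e5, nu, eta)
  v <- v[v != 0]
  sig <- ctx1$c / v
  ks <- max(abs(seq_along(sig) / length(sig) -
                noise_cdf_exact(sort(sig), nu, eta, ctx1)))
  expect_lt(ks, 1.63 / sqrt(length(sig)))
})

test_that("negative drift probability values", {
  expect_equal(negative_drift_prob(0, 1), 0.5)
  expect_equal(negative_drift_prob(2, 0), 0)
  expect_equal(negative_drift_prob(0.133, 0.12), pnorm(-0.133 / 0.12))
  expect_equal(round(negative_drift_prob(0.133, 0.12), 3), 0.134)
})

test_that("approximation fit: supports, ratio identity, flip equality", {
  e <- eddm_params(mean_drift = 0.133, drift_sd = 0.12, boundary = 1.3863,
                   mean_bias = 0, bias_spread = 0.08, mean_ndt = 0.4,
                   diffusion = 0.1)
  a <- approximate_ebm_from_eddm(e, ctx1)
  # prior: support matching of the exact support endpoints
  expect_equal(a$mean_prior, (plogis(-0.04) + plogis(0.04)) / 2)
  expect_equal(a$prior_spread, plogis(0.04) - plogis(-0.04))
  # ratio identity 1/sqrt(mean_noise * noise_var) == mean_drift/drift_sd
  expect_lt(abs(1 / sqrt(a$mean_noise * a$noise_var) - 0.133 / 0.12), 1e-8)
  # flip probability of the approximation equals the exact negative-drift
  # probability
  expect_lt(abs(flip_probability(a$mean_noise, a$noise_var) -
                negative_drift_prob(0.133, 0.12)), 1e-8)
  # median matching: IG median equals the positive-branch median
  med_ig <- uniroot(function(q) pinvgauss(q, a$mean_noise,
                                          1 / a$noise_var) - 0.5,
                    c(1, 1000))$root
  cdf_pos <- function(s) {
    (noise_cdf_exact(s, 0.133, 0.12, ctx1) -
       negative_drift_prob(0.133, 0.12)) /
      (1 - negative_drift_prob(0.133, 0.12))
  }
  expect_lt(abs(cdf_pos(med_ig) - 0.5), 1e-5) # root-finder tolerance
})

test_that("approximation fit: degenerate spreads give zero-spread eBM", {
  e <- eddm_params(mean_drift = 2, drift_sd = 0, boundary = 1.3863,
                   mean_bias = 0, bias_spread = 0, mean_ndt = 0.4)
  a <- approximate_ebm_from_eddm(e, ctx25)
  expect_identical(a$noise_var, 0)
  expect_identical(a$prior_spread, 0)
  expect_equal(a$mean_prior, 0.5)
  expect_equal(a$mean_noise, abs(ctx25$c) / 2)
})

test_that("translated pDDM reproduces pDDM response distributions", {
  set.seed(4)
  for (i in 1:3) {
    p <- pddm_params(drift = runif(1, 1, 5), boundary = runif(1, 1, 2),
                     bias = runif(1, -0.3, 0.3), ndt = 0.35)
    b <- pddm_to_bm(p, ctx25)
    rp <- simulate_pddm(p, 50000, seed = 40 + i)
    rb <- simulate_bm(b, 50000, seed = 60 + i, true_alternative = 1)
    q <- c(0.1, 0.3, 0.5, 0.7, 0.9)
    # both lattices step at dt = 0.05: agreement within one step
    expect_lt(max(abs(quantile(rp$rt[!rp$timed_out], q) -
                      quantile(rb$rt[!rb$timed_out], q))), 0.05 + 1e-9)
    expect_prop_close(mean(rb$choice[!rb$timed_out] == 1),
                      mean(rp$choice[!rp$timed_out] == 1), 50000, sds = 5)
  }
})

test_that("eDDM sampled through the exact maps matches direct eDDM", {
  e <- eddm_params(mean_drift = 3, drift_sd = 1.5, boundary = 1.3863,
                   mean_bias = 0, bias_spread = 0.4, mean_ndt = 0.4,
                   ndt_spread = 0.2)
  r1 <- simulate_eddm(e, 50000, seed = 71)
  r2 <- simulate_eddm_via_bm(e, ctx25, 50000, seed = 72)
  q <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  for (correct in c(TRUE, FALSE)) {
    q1 <- quantile(r1$rt[!r1$timed_out & (r1$choice == 1) == correct], q)
    q2 <- quantile(r2$rt[!r2$timed_out & (r2$choice == 1) == correct], q)
    expect_lt(max(abs(q1 - q2)), 0.06)
  }
  expect_prop_close(mean(r2$choice[!r2$timed_out] == 1),
                    mean(r1$choice[!r1$timed_out] == 1), 50000, sds = 5)
})
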