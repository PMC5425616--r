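# Shared fixtures. The "sweep world" is the fixed parameter set of the
# simulation experiments: bound 0.8, mean prior 0.5, ndt 0.4 +/- 0.1,
# feature means +/-25, dt 0.05, 5 s timeout.

sweep_world_ebm <- function(mean_noise = 222.5538, noise_var = 0,
                            prior_spread = 0, ...) {
  ebm_params(bound = 0.8, mean_noise = mean_noise, noise_var = noise_var,
             mean_prior = 0.5, prior_spread = prior_spread, ndt = 0.4,
             ndt_spread = 0.2, feature_means = c(25, -25), dt = 0.05,
             max_rt = 5, ...)
}

sweep_world_bm <- function(noise = 222.5538, ...) {
  bm_params(bound = 0.8, noise = noise, prior = 0.5, ndt = 0.4,
            ndt_spread = 0.2, feature_means = c(25, -25), dt = 0.05,
            max_rt = 5, ...)
}

# closed-form first-passage probability of the continuous Wiener process
# with drift v, diffusion s, symmetric bounds +/-B, start z
wiener_upper_prob <- function(v, s, B, z) {
  if (v == 0) return((z + B) / (2 * B))
  x <- exp(-2 * v * (z + B) / s^2)
  a <- exp(-4 * v * B / s^2)
  (1 - x) / (1 - a)
}

expect_prop_close <- function(phat, p, n, sds = 4) {
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(phat - p), sds * se + 1e-12)
}
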