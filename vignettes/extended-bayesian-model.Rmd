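---
title: "Extended Bayesian decision models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended Bayesian decision models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebdm)
```

# The models

## Drift diffusion

The pure drift-diffusion model (pDDM) describes a two-alternative decision
as a discretized Wiener process: the decision variable $y_t$ starts at the
bias $z$ and moves each step of length $\Delta t$ by a Gaussian increment
with mean $v\,\Delta t$ (drift $v$) and standard deviation
$\sqrt{\Delta t}\,s$ (diffusion $s$), until it crosses $+B$ (choice 1) or
$-B$ (choice 2). A non-decision time $T_{nd}$ is added to the crossing
time. The extended model (eDDM) redraws three parameters on every trial:
drift $\sim \mathrm{Normal}(\bar v, \eta)$, bias
$\sim \mathrm{Uniform}(\bar z \pm s_z/2)$, and non-decision time
$\sim \mathrm{Uniform}(\bar T_{nd} \pm s_t/2)$. Drift variability produces
slow errors, bias variability fast errors.

## The Bayesian reformulation

The Bayesian model (BM) replaces the abstract accumulator with inference
about which alternative generated a stream of noisy stimulus features
$x_t \sim \mathrm{Normal}(\mu_{i}, \Delta t\,\sigma^2)$, where $\mu_i$ is
the feature mean of the true alternative and $\sigma$ the noise level. The
decision maker scores each observation under per-alternative generative
models $\mathrm{Normal}(\hat\mu_i, \Delta t\,\hat\sigma^2)$, updates the
posterior over alternatives by Bayes' rule, and commits when any posterior
reaches the bound $\lambda$.

For two alternatives the posterior log-odds is a Gaussian random walk, and
with the parameter maps

$$\lambda = \mathrm{logistic}(B), \qquad p_0 = \mathrm{logistic}(z),
\qquad \sigma = \frac{s\,\mu_{i(r)}}{\Delta t\, v},$$

together with the internal-uncertainty coupling

$$\hat\sigma^2 = \frac{\sigma\,\lvert\hat\mu_1-\hat\mu_2\rvert}{\Delta t\, s},$$

the walk's increments have mean $v\,\Delta t$ and standard deviation
$s\sqrt{\Delta t}$ exactly — the BM and the pDDM are the same stochastic
process expressed in different coordinates. The package exploits this both
ways: `pddm_to_bm()` / `bm_to_pddm()` implement the maps, and the test
suite verifies that simulated response distributions of the two routes
coincide.

A note on the coupling: the product form
$\hat\sigma^2 = \sigma\,\Delta t\,s\,\lvert\hat\mu_1-\hat\mu_2\rvert$
sometimes seen in secondary renderings of this equation is a typographic
corruption of the fraction above; only the fraction is consistent with the
three parameter maps (substitute $\sigma = s\mu/(\Delta t\,v)$ and
$\hat\sigma^2 = \mu(\hat\mu_1-\hat\mu_2)/(\Delta t^2 v)$) and only the
fraction reproduces the reference sweep behaviour (with feature means
$\pm 25$, $s = 2.8$, $\Delta t = 0.05$, the accuracy floor of 0.55 at mean
noise 2500 follows from the equivalent drift $v = 1400/\sigma$).

## Inter-trial variability (eBM)

The extended BM (eBM) mirrors the eDDM's variabilities in the Bayesian
coordinates. Pushing the uniform bias density through the logistic map
gives the exact prior density
$f(p_0) = 1/\bigl(s_z\,(p_0 - p_0^2)\bigr)$ on the transformed support
(`prior_density_exact()`), which the eBM approximates by a uniform with
support-matched endpoints. Pushing the Gaussian drift through
$\sigma = c/v$, $c = s\,\mu_{i(r)}/\Delta t$, gives the exact signed
noise-level density $f(\sigma) = f_V(c/\sigma)\,\lvert c\rvert/\sigma^2$
(`noise_density_exact()`); its negative branch is the image of negative
drift samples — trials whose input points at the wrong alternative. The
eBM approximates the positive branch by an inverse Gaussian with mean
$\bar\sigma$ and shape $1/\eta_N$ and replaces the negative branch by a
Bernoulli "input flip" with probability
$P_{NT} = \Phi\!\bigl(-1/\sqrt{\bar\sigma\,\eta_N}\bigr)$, the exact
Gaussian negative-drift probability evaluated at the matched
mean-to-standard-deviation ratio.

Per simulated trial the eBM draws a noise level (inverse Gaussian, exact
Michael–Schucany–Haas sampler, rationalized to avoid the catastrophic
cancellation of the textbook formula at small shape), recomputes the
internal uncertainty from the *sampled* noise level — this coupling is what
mixes fast/low-error with slow/high-error trials and produces slow errors —
draws a prior (uniform), flips the input sign with probability $P_{NT}$,
draws a non-decision time (uniform, truncated at 0), accumulates to the
bound, and finally applies the lapse model (random choice, uniform RT, a
lapse timed out with probability $\pi_{to}$).

## Fitting the approximation

`approximate_ebm_from_eddm()` turns eDDM parameters into eBM parameters.
The prior side is support matching. The noise side fixes
$\bar\sigma\,\eta_N = (\eta/\bar v)^2$ exactly (so the flip probability
equals the negative-drift probability to machine precision) and pins
$\bar\sigma$ by matching the *median* of the exact density's positive
branch. Median rather than moment matching is a deliberate deviation from
the naive recipe: the positive branch of $f(\sigma)$ has a $1/\sigma$ tail
(the Gaussian drift has positive density at $v = 0$), so its mean is
infinite and moment matching is undefined. The median is well defined,
closed-form on the exact side, and found for the inverse Gaussian by a
bracketed root search (tolerance $10^{-10}$).

Illustrative fitted values sometimes quoted for this approximation (for
example a prior spread of 0.508 for a bias spread of 0.08) are not
reproducible from any support- or quantile-matching rule and are treated
as illustrative only; no test asserts them.

# Exact-input models and the synthetic task

The exact-input variants (EXaM, eEXaM) replace the Gaussian input stream
by the actual per-trial stimulus feature sequence: one observation per
stimulus frame, $\Delta t$ equal to the frame duration. The synthetic task
generator (`generate_dot_stimuli()`) emulates a single-dot location
discrimination: two targets at $\pm$10/25/40/55 px from center, one dot
position every 93.2 ms, at most 25 frames (2.33 s timeout), 200 trials per
condition, balanced targets.

What the generator does *not* emulate: the spatial rendering of the dot
(only its x-position matters to the models), any temporal correlation in
the dot path (frames are i.i.d.), and the exact dot-position spread used
in the original display, which is not printed in the source material. The
spread is therefore a free parameter with a fixed default of 35 px, chosen
once so that the hardest condition yields about 70% accuracy under the
canonical bound of 0.8 with a matched internal model (and implying an
effective noise level of $35/\sqrt{0.0932} \approx 115$ px s$^{-1/2}$, the
order of magnitude recovered when such data are fitted). A green
exact-input test therefore establishes internal consistency of the model
chain, not fidelity to the original display.

Because the generator draws frames i.i.d. Gaussian around the target, an
exact-input run on synthetic stimuli with dot spread $sd$ is
distributionally identical to a DDM-equivalent run with noise level
$sd/\sqrt{\Delta t}$ — a property the test suite checks and a useful
sanity anchor between the two input modes.

# Simulation experiments

Two sweep experiments reproduce classic behavioural phenomena with fixed
parameters (bound 0.8, mean prior 0.5, non-decision time 0.4 s $\pm$ 0.1,
feature means $\pm 25$, $\Delta t = 0.05$ s, 5 s timeout):

* task difficulty — grid over mean noise level $[25, 2500]$ (log) and
  noise variability $[10^{-4}, 10^{-2}]$ (log), prior spread 0.2;
  accuracy spans about 0.55–1.0 and median RT about 450–720 ms;
* slow/fast errors — grid over noise variability (log) and prior spread
  $[0, 0.3584]$ (linear) at mean noise 222.5538; the correct-minus-error
  median RT difference spans about $-40$ to $+30$ ms, positive (fast
  errors) at large prior spread with small noise variability, negative
  (slow errors) whenever the noise variability is large.

Grid resolution is not dictated by the protocol; the default is 20 x 20,
log-spaced in the scale parameters and linear in the prior spread.
Timed-out trials (RT above the timeout) are excluded from both accuracy
and RT statistics; the protocol only says they are "marked", and exclusion
is the conventional reading. RT quantiles interpolate linearly between
order statistics (R's default type 7).

# Inference

Fitting is likelihood-free. Parameters live in an unconstrained Gaussian
space; an exponential transformation yields log-normal marginals for scale
parameters and a Gaussian-CDF transformation yields (possibly biased)
bounded marginals for probabilities. The standard priors are: bound and
mean prior uniform on (0,1); mean noise log-normal(5,1); noise variability
log-normal(-10,3); non-decision time log-normal(-1.5,1); its spread
log-normal(-2,1); prior spread and lapse probability bounded through
Normal(-2,1) and Normal(-1,1) respectively — for these two the reference table gives Gaussian moments without naming the transformation; the
bounded (CDF) kind is inferred from the depicted prior shapes and flagged
here for review; timeout-lapse probability uniform(0,1).

The acceptance kernel accepts a simulated response for an observed trial
when the choice matches and the RTs differ by at most $\varepsilon$ (0.05 s);
timed-out trials are matched on the timeout flag, since the reference protocol
is silent about them and an RT comparison against a censored value would
be meaningless.

`epabc_fit()` implements trial-wise EP-ABC: one Gaussian site per trial,
cavity sampling, one simulated response per parameter draw, moment
matching of accepted draws with damping `alpha`, a relative variance floor
`veps` (site covariance diagonals are floored at `veps` times the cavity
diagonal — the cited reference leaves the floor's exact form open),
rejection of updates that break positive definiteness, and a configurable
number of passes. The marginal likelihood is assembled from the site
normalizers in the standard EP form.

`abc_fit()` is the no-EP fallback. A literal rejection sampler with the
product kernel over 200 trials has acceptance probability near zero, so
the fallback is an annealed importance sampler with the same kernel: the
estimated log likelihood (shared reference simulations across the i.i.d.
trials of a condition; probabilities floored at half a count) is tempered
by an exponent that rises adaptively — each stage raises it as far as it
can while keeping the effective sample size above a fraction of the
stage's own noise floor — with multivariate-t proposals refitted between
stages, until the full likelihood (exponent 1) is reached. Two further
variance-reduction choices matter: the uniform non-decision time and the
lapse mixture are integrated analytically given the simulated crossing
times (same kernel, smaller estimator variance), and the final stage uses
a larger reference batch. The returned posterior is the weighted Gaussian
fit in transformed space plus the weighted draws; credible intervals use
weighted sample quantiles of the transformed draws. The log marginal
likelihood is the final-stage importance-sampling estimate.

Model comparison uses random-effects Bayesian model selection: variational
Dirichlet estimation of population model frequencies, exceedance
probabilities by Dirichlet sampling (10^6 draws by default — no sampling count is prescribed by the procedure; this is standard practice), and
protection through the Bayes omnibus risk,
$\mathrm{pxp} = (1-\mathrm{bor})\,\mathrm{ep} + \mathrm{bor}/K$. Families
are handled by aggregating member frequencies and exceedance mass over a
partition.

# Numerical and design choices

* Accumulation is carried in log space throughout (posterior updates
  subtract the maximum before exponentiating); the two-alternative fast
  path works directly on the posterior log-odds.
* Both of `p_0 < \lambda` and `1 - p_0 < \lambda` are enforced, though
  only the former is usually stated: without the latter the model would
  choose alternative 2 at step 0.
* Crossing exactly at a bound counts as a decision; the posterior at step
  0 is the prior; a crossing at step $k$ contributes decision time
  $k\,\Delta t$; RTs are not jittered within a step.
* Non-decision-time samples are truncated at 0.
* Trials undecided at the timeout, and decided trials whose total RT
  exceeds it, are flagged timed out and carry the timeout as RT.
* Simulators are deterministic for a fixed `(seed, n_trials)`. Trial-level
  parameters are drawn in one block and all trials then advance together;
  per-trial independent random streams (which would make early trials
  invariant to `n_trials`) were dropped deliberately — they would force a
  scalar per-trial loop roughly fifty times slower, incompatible with the
  sweep experiments.
* The bias-spread constraint is enforced two-sidedly
  (`mean_bias ± bias_spread/2` strictly inside the boundaries); the
  constraint is usually printed in an ambiguous one-line form.
* Density normalization checks use adaptive quadrature with absolute
  tolerance $10^{-8}$ or better.
* The inverse-Gaussian flip indicator is drawn independently of the
  sampled noise magnitude. The exact change-of-variables density couples
  the two (large noise and flipped input both come from small drifts); the
  approximation deliberately separates them, and the equivalence checks
  bound the consequences.

# Known limitations

* Decision times live on the $\Delta t$ lattice, so RT distributions are
  discrete mixtures smoothed only by the non-decision-time spread;
  quantile comparisons between two simulation routes can differ by up to
  one step.
* `abc_fit()` assumes the trials of a condition are i.i.d. given the
  parameters and is therefore not applicable to the exact-input models;
  fit those with `epabc_fit()`, which is trial-wise by construction.
* The EP-ABC marginal likelihood inherits the usual EP caveats (single
  Gaussian, site damping); use it for model ranking, not as an absolute
  evidence value.
* Posterior effective sample sizes of `abc_fit()` are modest (tens to a
  few hundred); interval endpoints carry corresponding Monte-Carlo error.
* M > 2 alternatives are supported by the reference trial runner
  (`run_bm_trial()`) but not by the vectorized batch simulators, which are
  two-alternative throughout.
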