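# ebdm — extended Bayesian decision models for perceptual decisions

`ebdm` is an R package for simulating and fitting sequential-sampling
models of two-alternative perceptual decisions. It is aimed at researchers
who model choice and response-time (RT) data — e.g. from random-dot-motion
or dot-localization tasks — and want the explanatory reach of the extended
drift-diffusion model together with an explicit account of how stimulus
features become decision evidence.

## The models

The **pure drift-diffusion model** (pDDM) accumulates evidence $y_t$ in
steps of length $\Delta t$,

$$y_t - y_{t-\Delta t} = v\,\Delta t + \sqrt{\Delta t}\,s\,\varepsilon_t,
\qquad \varepsilon_t \sim \mathcal N(0,1),$$

from a starting point $z$ to absorbing bounds $\pm B$; the **extended**
model (eDDM) redraws drift (Gaussian, sd $\eta$), starting point (uniform,
width $s_z$) and non-decision time (uniform, width $s_t$) on every trial.

The **Bayesian model** (BM) recasts the same process as inference: noisy
stimulus features $x_t \sim \mathcal N(\mu_i, \Delta t\,\sigma^2)$ are
scored under per-alternative generative models of width $\hat\sigma$
(coupled to the noise level by
$\hat\sigma^2 = \sigma\,|\hat\mu_1-\hat\mu_2| / (\Delta t\,s)$), the
posterior over alternatives is updated recursively, and a decision is made
when it reaches the bound $\lambda$. With
$\lambda = \mathrm{logistic}(B)$, $p_0 = \mathrm{logistic}(z)$ and
$\sigma = s\,\mu_{i(r)}/(\Delta t\,v)$, the BM and pDDM are the *same*
process. The **extended Bayesian model** (eBM) carries the eDDM's
inter-trial variabilities into these coordinates: the noise level varies
as an inverse Gaussian (mean $\bar\sigma$, variability $\eta_N$), the
prior as a uniform (width $s_P$), and with probability
$\Phi(-1/\sqrt{\bar\sigma\eta_N})$ a trial's input points at the wrong
alternative — the image of a negative drift sample. Exact
change-of-variables densities for both translations, and the
uniform/inverse-Gaussian approximation fit, are part of the package. The
**exact-input models** (EXaM, eEXaM) feed the actual per-trial stimulus
sequence (dot positions per frame) into the same machinery.

Fitting is likelihood-free (choice/RT acceptance kernel, $\varepsilon$ =
0.05 s): trial-wise EP-ABC (`epabc_fit()`) or an annealed
importance-sampling fallback (`abc_fit()`), with random-effects Bayesian
model selection (`rfx_bms()`, protected exceedance probabilities) on the
resulting marginal likelihoods.

## A worked example

Simulate the slow-error regime of the eBM and summarize it:

```r
library(ebdm)
e <- ebm_params(bound = 0.8, mean_noise = 222.5538, noise_var = 0.001,
                prior_spread = 0.014, ndt = 0.4, ndt_spread = 0.2)
r <- simulate_ebm(e, 1e5, seed = 42)
summarize_responses(r)
#> response_summary: 100000 trials (0.0% timed out)
#>   proportion correct 0.924 | median RT 595 ms (correct 593, error 629)
```

Errors are *slower* than correct responses (629 vs 593 ms median): trials
that drew a high noise level produce both more errors and slower
decisions, and mixing them with fast low-noise trials skews the error
distribution — the classic slow-error signature, here produced by noise
variability alone. The 30th RT percentiles of this run are 531 ms
(correct) vs 552 ms (error), and the 90th are 873 vs 973 ms: the effect
grows along the RT distribution. Swapping the variability pattern
(`noise_var = 1e-4`, `prior_spread = 0.35`) produces fast errors instead.

The exact equivalence in action:

```r
p <- pddm_params(drift = 4, boundary = 1.3863, bias = 0.2, ndt = 0.35)
b <- pddm_to_bm(p, translation_context(25))
b$bound                       # 0.8  (logistic of the boundary)
quantile(simulate_pddm(p, 1e5, seed = 3)$rt, c(.1, .5, .9))
#>  0.45 0.60 0.95
quantile(simulate_bm(b, 1e5, seed = 4, true_alternative = 1)$rt,
         c(.1, .5, .9))
#>  0.45 0.60 0.95
```

A command-line interface mirrors the library
(`inst/exec/ebdm simulate --model ebm ...`, `translate`, `sweep`, `fit`,
`compare`).

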