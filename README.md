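# phagedyn

Phage–bacteria community dynamics: compartmental SEIV/SEIVD infection
models, life-history-trait inference, and density-dependent infection
attenuation.

## What it is for

Lytic phage life-history traits — the adsorption rate φ (ml/h), mean latent
period τ (h), its coefficient of variation, and burst size β — are usually
measured in short pairwise assays and then extrapolated to community
dynamics. That extrapolation predicts rapid bacterial collapse within a few
lytic cycles, while real multi-strain phage–bacteria communities coexist at
high densities. `phagedyn` is for researchers who want to quantify this gap
and the mechanisms that close it: it provides

* **Infection models.** The pairwise SEIV model (susceptible → Erlang chain
  of exposed stages → infected → lysis, free virions), its SEIVD extension
  in which accumulated lysed-cell debris D attenuates new infection through
  a Hill feedback `1/(1 + (D/D_c)^2)`, and community-scale versions for any
  host-range matrix (pair-specific traits, one shared debris pool, per-host
  critical debris concentrations `D_c_i`). The latent period uses the linear
  chain trick: `n_e` exposed stages plus a terminal infected stage at rate
  `(n_e + 1)/τ` give mean τ and CV `1/sqrt(n_e + 1)`.
* **Conventional trait estimators** from growth curves, adsorption assays,
  and one-step growth curves, including the burst-size ratio
  `⟨β⟩ = (⟨V₂⟩ − ⟨V₁⟩)/(⟨T₁⟩ − ⟨V₁⟩)` and the first-rise latent period
  (systematically biased below the true mean when the latent period varies).
* **Bayesian inference** by a delayed-rejection adaptive Metropolis (DRAM)
  sampler with truncated-normal/log-normal priors, Gaussian likelihoods on
  log10 densities, coordinate-descent prior centring, split-R-hat and
  effective-sample-size diagnostics, posterior-predictive envelopes, and a
  Bayesian test of practical equivalence (`p_eq` against a ROPE) for
  comparing pairwise- versus community-inferred traits.
* **Synthetic-data generators** that emulate the study designs — one-step
  growth curves (15-min adsorption, 1:100 dilution), multi-cycle pairwise
  infections (MOI 0.1 from 2×10⁶ cells/ml), and a five-host/five-phage
  community sampled every 35 min for 15.75 h in triplicate — with
  multiplicative lognormal noise, detection-floor censoring, and a
  ground-truth manifest for parameter-recovery benchmarks.

Everything is tidyverse-shaped: generators and estimators take and return
tibbles, fitted objects have `tidy()`/`glance()` methods, and datasets,
trajectories, posteriors and predictive envelopes have `autoplot()` methods.

## Worked example

```r
library(phagedyn)

# ground truth: an aggressive lytic pair (latent-period CV 0.1)
truth <- trait_set(r = log(2) / 4, phi = 1e-7, tau = 1, n_e = 99, beta = 50)

# 1. simulate a one-step growth experiment with 10% lognormal noise
onestep <- generate_onestep(truth, noise = noise_model(sigma = 0.1), seed = 11)

# 2. conventional estimates
estimate_traits(onestep = onestep)[, c("latent_period_h", "beta")]
#>   latent_period_h  beta
#> 1           0.760  48.1

# 3. Bayesian SEIV fit by DRAM (r fixed from growth assays)
fit <- fit_pairwise_onestep(onestep, r = truth$r, n_steps = 2000, seed = 7)
tidy(fit)[1:5, c("parameter", "median", "conf.low", "conf.high")]
#>   parameter       median      conf.low     conf.high
#> 1 phi        0.000000101  0.0000000969   0.000000104
#> 2 tau        1.00         0.990          1.02
#> 3 n_e       98.6         84.0          111.
#> 4 beta      49.8         47.0           52.7
#> 5 sigma      0.0945       0.0888         0.106

posterior_predictive(fit, n_draws = 100, seed = 1)
#> <posterior_predictive> 100 draws, 95% band coverage 0.937
```

The first-rise latent period (0.76 h) underestimates the true mean (1 h)
because the earliest-lysing cells burst first; the Bayesian fit recovers φ,
τ, β and the stage count `n_e` (hence the latent-period CV) from the same
data, and 93.7% of the observations fall inside the 95% posterior-predictive
band.

Forecasting multiple cycles with the fitted traits predicts a host crash:

```r
med <- tidy(fit)$median
fitted <- trait_set(r = truth$r, phi = med[1], tau = med[2],
                    n_e = round(med[3]), beta = med[4])
crash <- integrate_dynamics(pairwise_model(fitted), list(S = 2e6, V = 2e5),
                            seq(0, 15.75, 0.25))
min(observe(crash, "host_qINT")$value)
#> [1] 0.0001862481
```

— a collapse from 2×10⁶ cells/ml to below one cell per 1000 litres. A finite
critical debris concentration (`trait_set(..., d_c = 3e5)`) turns the same
forecast into host persistence above 10⁵ cells/ml; `fit_community()` infers
per-pair traits and per-host `D_c_i` jointly from community qPCR series, and
`equivalence_test()` quantifies which traits shifted between the pairwise and
community contexts.

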