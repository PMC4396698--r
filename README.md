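# profregts — Bayesian profile regression for multipollutant time series

Airborne particles are a correlated mixture — particle number counts,
chloride, nitrate, sulphate, black smoke, gravimetric masses and
source-apportioned fractions — yet short-term health effects are usually
estimated one pollutant at a time. `profregts` implements the
profile-regression alternative for daily time series: a Dirichlet-process
mixture jointly clusters days by their multipollutant exposure profile *and*
links cluster membership to a Poisson model for daily deaths, while natural
cubic splines of calendar time and temperature absorb trend, seasonality and
weather. The number of clusters is inferred, clustering uncertainty is
quantified, and days with missing measurements stay in the analysis (missing
values are imputed inside the sampler).

The model, for day `t` with count `y_t`, lagged exposure profile `z_t` and
spline row `u_t`:

```
p(y_t, z_t | Θ, u_t) = Σ_k  w_k · p(y_t | Θ_k, Θ_0, u_t) · p(z_t | Θ_k)

z_t | g_t = k  ~  MVN(m_k, Σ_k)
y_t | g_t = k  ~  Poisson( E · exp( μ_k + Σ_h β_h u_{t,h} + ε_t ) )
```

with stick-breaking weights `w_k = V_k Π_{i<k}(1−V_i)`, `V_k ~ Beta(1, α)`,
`α ~ Gamma(2, 1)`; empirical-Bayes Normal/Wishart hyperpriors on
`(m_k, Σ_k⁻¹)`; Student-t(7, 0, 2.5) priors on `β` and `μ_k`; and a
Gaussian day effect `ε_t` for extra-Poisson variation. The offset `E` is the
period-average count, so `exp(μ_k)` is the relative risk of cluster-`k`
days against the average. Inference is a dependent-slice MCMC sampler
(Gibbs + Metropolis-within-Gibbs, label-switching moves, within-sampler
imputation); post-processing turns the chain into a representative
partition (PAM on 1 − posterior similarity) with model-averaged cluster
profiles and risks; posterior predictive machinery compares exposure
scenarios as a percent change in expected deaths.

See `vignettes/profile-regression.Rmd` for the full model account, sampler
design, and limitations.

## Worked example

Everything below runs on synthetic data; `preset_recovery()` generates 730
days of 6 correlated metrics in three latent groups (weights 0.6/0.25/0.15)
whose log relative risks are −0.3 / 0 / +0.3 around a baseline of 21.6
deaths/day:

```r
library(profregts)

series <- simulate_profile_series(preset_recovery(seed = 42))
fit <- profile_regression(series, mcmc = mcmc_config_small(seed = 7))
fit
#> rep_partition: 3 clusters of sizes 432/194/103 (avg silhouette 0.997)
#> cluster 1 (432 days): RR 0.809 (0.787, 0.832)
#> cluster 2 (194 days): RR 1.108 (1.067, 1.149)
#> cluster 3 (103 days): RR 1.526 (1.461, 1.593)

adjusted_rand(fit$partition$labels, fit$data$true_labels)
#> [1] 0.9952243
```

The three generated groups are recovered almost exactly (adjusted Rand
index 0.995), and the model-averaged relative risks match the generative
truth *relative to the period average* — with the offset equal to the mean
count, the identifiable risks are `exp(lrr_k) / Σ_j f_j exp(lrr_j)` =
0.83 / 1.12 / 1.51 for these weights, and each 95% credible interval above
covers its target. `fit$summaries$profiles` carries the per-cluster
exposure profiles (normalised and original scale),
`membership_probabilities(fit$chain, fit$partition)` the per-day allocation
uncertainty, and `chain_diagnostics(fit$chain)` the global traces and
effective sample sizes.

Scenario comparison and validation:

```r
cv <- cross_validate(series, split_date = series$dates[549],
                     mcmc = mcmc_config_small(seed = 29))
cv$coverage        # ~0.95: held-out daily counts inside 95% predictive intervals
```

`run_full_analysis(series, "out/")` executes the whole pipeline and writes
similarity matrix, partition, risk and profile tables, membership
probabilities, diagnostics, a manifest and a short report;
`run_sensitivity()` refits under alternative Gamma priors for the DP
concentration and reports occupied-cluster counts and pairwise partition
agreement.

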