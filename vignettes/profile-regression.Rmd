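---
title: "Joint clustering of multipollutant profiles and daily mortality: model and methods"
author: "profregts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint clustering of multipollutant profiles and daily mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Short-term health effects of airborne particles are usually estimated one
pollutant at a time, treating the rest of the mixture as confounders.  But
particles arrive as a correlated mixture — number counts, inorganic anions,
black smoke, gravimetric masses, source-apportioned fractions — and the
policy-relevant question is how *mixtures* relate to daily mortality.
`profregts` takes the profile-regression view: days are clustered by their
multipollutant exposure profile with a Dirichlet-process (DP) mixture, and
cluster membership simultaneously enters a Poisson model for the daily death
count.  Clusters are therefore informed by both the exposure space and the
health outcome, the number of clusters is inferred rather than fixed, and
days with partially missing measurements stay in the analysis.

## The model

Let `y_t` be the death count on day `t = 1..T`, `z_t` a vector of `P`
normalised exposure metrics measured the day before (1-day lag by default),
and `u_t` a row of fixed natural-cubic-spline bases in calendar time and
temperature.  The joint model is

    p(y_t, z_t | Theta, u_t) = sum_k w_k p(y_t | Theta_k, Theta_0, u_t) p(z_t | Theta_k)

with stick-breaking weights `w_1 = V_1`, `w_k = V_k prod_{i<k} (1 - V_i)`,
`V_k ~ Beta(1, alpha)` and `alpha ~ Gamma(a, b)` (defaults `a = 2, b = 1`).
Within cluster `k` the exposures are multivariate normal,
`z_t ~ N(m_k, Sigma_k)`, and the response is Poisson,

    y_t ~ Poisson(E exp(mu_{g_t} + sum_h beta_h u_{t,h} + eps_t)),

where `E` is the constant offset (the period-average daily count, so
`exp(mu_k)` reads as the relative risk of cluster-`k` days against the
period average), `eps_t ~ N(0, sigma_eps^2)` absorbs extra-Poisson
day-to-day variation, and the spline terms have a global effect only —
confounder control is not cluster-specific.

Hyperpriors are empirical-Bayes: `m_k ~ N(m0, Sigma0)` with `m0` the column
means and `Sigma0` diagonal with squared column ranges; the precision
`Q_k = Sigma_k^{-1} ~ Wishart(Phi, nu)` with `nu = P` and
`Phi = diag(1/variance)/P`, read element-wise from the per-column empirical
variances.  Whether that scale matrix should instead be the inverse of the
full empirical covariance is genuinely ambiguous; the diagonal reading is
the default and `phi_mode = "full"` exposes the alternative.  The spline
coefficients and the cluster log relative risks both carry weakly
informative Student-t(7, 0, 2.5) priors (the `mu_k` prior is our choice,
mirroring the stated `beta` prior, since no prior for `mu_k` is prescribed).
The day-effect precision `tau = sigma_eps^{-2}` has a Gamma(5, 0.5) prior —
weakly informative around `sigma_eps ~ 0.3` on the log-rate scale.

### Identifiability of the overall level

Only differences of `mu_k` are informed by the likelihood once an arbitrary
constant can hide elsewhere in the linear predictor.  Two measures pin the
level down:

* spline basis columns are **centred over the training days** (the standard
  additive-model constraint), so the smooths cannot absorb a constant;
* the day effects carry a zero-mean prior, and the sampler includes
  recentering moves (below) that transfer any systematic within-cluster
  mean of `eps` into `mu_k`.

With these, `exp(mu_k)` estimates the cluster's rate relative to the period
average — which is also the only version of "relative risk" the data can
identify when the offset is the observed mean count.

## Preprocessing

* **Modified z-score**: `z = (x - median) / median(|x - median|)` per
  metric, computed over observed entries; a zero MAD is an explicit error
  (silent rescaling would corrupt the cluster geometry).  Medians and MADs
  are stored so profiles and scenarios can move between scales.
* **Lag alignment is by date**, not row position: an outcome day whose
  lagged exposure date is absent is dropped rather than mispaired.
* **Spline df**: defaults are 8 df per year for calendar time and 3 df for
  temperature.  `select_df()` reproduces the selection procedure — a
  log-linear Poisson fit with offset per candidate df, AIC/BIC tabulated,
  minimum AIC chosen with ties to the smaller df, and the PACF of deviance
  residuals returned for inspection.  The candidate bases are fitted
  jointly (time and temperature together); whether the original selection
  was joint or per-variable is not documented, and the joint fit is our
  assumption.
* Bases are built once and passed to the sampler as fixed data; they are
  never rebuilt per sweep.

## Posterior computation

Inference is a dependent-slice sampler: an auxiliary uniform `u_t` on
`(0, xi_{g_t})` with deterministic levels `xi_k = (1 - rho) rho^{k-1}`
(`rho = 0.75`) makes the candidate set `{k : xi_k > u_t}` finite each sweep,
so no truncation level is ever imposed; cluster storage grows lazily to
whatever index the slice exposes and empty clusters are refreshed from the
prior.  The sweep order is: allocations (Gumbel-max categorical draw over
the candidate set, with the marginal MVN density over observed coordinates
for days with missing cells) → stick and concentration conditionals (Beta
and Gamma conjugate forms) → cluster locations and precisions
(Normal–Normal and Wishart conjugate draws) → response parameters → missing
exposure imputation (conditional MVN of the allocated cluster) → label
moves.

The response block uses random-walk Metropolis for `mu_k` (on per-cluster
sufficient sums) and for each `beta_h`, a single vectorised elementwise
Metropolis step for all `eps_t` (they are conditionally independent), and
the conjugate Gamma draw for `tau`.  Proposal scales adapt towards 44%
acceptance in batches of 50 sweeps during burn-in only, preserving detailed
balance afterwards.

Two further move families matter in practice:

* **Recentering moves.**  `mu_k` and the cluster's day effects are only
  jointly identified through the `eps` prior, and the confounded direction
  (`mu_k + d`, `eps_t - d` for the cluster's days) mixes impossibly slowly
  under single-site updates.  We shift along this likelihood-invariant
  ridge, proposing `d` from the ridge conditional
  `N(mean(eps_k), sigma_eps^2/n_k)` so that the proposal ratio cancels the
  Gaussian term and acceptance reduces to the Student-t prior ratio.  The
  same move is applied per spline coefficient (`beta_h + d`,
  `eps - d u_h`).
* **Label-switching moves.**  Size-biased stick conditionals make naive
  (stick, contents) swaps essentially never acceptable, so two standard
  moves are used: swapping the *contents* (parameters and allocations) of
  two random clusters with acceptance `(w_k/w_j)^(n_j - n_k)`, and a
  neighbour swap with a weight-preserving transformation of
  `(V_j, V_{j+1})` — a deterministic involution accepted with its Jacobian
  `(1 - V_j)/(1 - V_j')`.  Both leave the posterior invariant and are
  individually switchable.

Defaults mirror the reference analysis settings: 70,000 sweeps, 20,000
burn-in, 1-in-10 thinning — exactly 5,000 stored draws.
`mcmc_config_small()` (10,000 / 3,000 / 5) is the scaled-down configuration
used for the package's simulation benchmarks, which run at T = 730 days and
P = 6 metrics; those sizes give comfortable recovery margins while keeping
a full benchmark suite runnable on a laptop.  The chain is a deterministic
function of its seed, and a non-finite joint density aborts with the sweep
number and cluster count.

The concentration conditional `alpha | V ~ Gamma(a + K+, b - sum log(1 - V_k))`
conditions on the sticks up to `K+`, the highest occupied index — the
self-consistent reading of "represented" sticks under the slice scheme.

## Post-processing

Every stored sweep contributes a co-clustering indicator; their average is
the posterior similarity matrix `S`.  Partitioning around medoids on
`1 - S` for each candidate `k` yields the representative partition, keeping
the `k` with the largest average silhouette width (ties to the smallest
`k`; the selection rule is ours, chosen because it is deterministic and
recovers block-structured truths).  Labels are relabelled by decreasing
cluster size.  Uncertainty is recovered by model averaging: in each sweep,
each day carries the parameters of the cluster it belongs to in that sweep;
averaging over a representative cluster's days gives one draw of the
cluster's profile and relative risk, summarised by the mean and central
(equal-tail) 95% interval — the tail convention is our choice.  Membership
probabilities report how often each day co-clusters with each
representative medoid; rows are normalised to sum to one because two
medoids can occasionally share a sweep-cluster.  Diagnostics cover the
global traces (concentration, `sigma_eps`, occupied clusters, data
log-likelihood) with autocorrelations and effective sample sizes.

## Scenario prediction

For a new exposure scenario (original units, normalised with the *training*
medians and MADs), each posterior draw allocates each scenario day to one of
its occupied clusters with probability proportional to
`w_k p(z* | Theta_k)`, then draws a count from
`Poisson(E exp(mu_k + confounder contribution + eps*))` with a fresh
`eps* ~ N(0, sigma_eps^2)` — predictive, not fitted, uncertainty.  The
calendar-time contribution is fixed at its training mean (scenario dates
lie outside the fitted spline's support; trend is a confounder, not a
transferable effect — `time_reference = "final_year"` is the alternative),
and the temperature contribution uses the scenario's own temperature when
provided.  This pseudo-profile allocation scheme is a documented
assumption: the reference analysis delegates its exact predictive
computation to supplementary material that is not available, so the scheme
above — allocation by exposure likelihood under each retained draw — is our
reconstruction of it.  Two scenarios are compared by the per-draw percent
change in total predicted counts, paired by posterior draw, with totals
truncated to equal day counts when lengths differ.  Predictive
cross-validation fits the model on a training window, predicts the held-out
days, and reports 95% predictive-interval coverage and mean absolute error.

## The synthetic-data generator

No monitoring or mortality data ship with the package, so the generator
emulates the structure the model assumes: days fall into `K_true` groups
with MVN profiles; the count on day `t` responds to the group of day
`t - 1` (matching the analysis exposure window — with iid group labels,
generating from the same-day group would make the lagged analysis signal
vanish); smooth confounding enters as a centred linear trend plus an annual
cosine plus a linear-in-temperature term; temperature itself is a sinusoid
(period 365.25 d, peak mid-July, mean 14 °C, amplitude 10.5 °C, noise sd
2 °C, spanning roughly −1 to 29 °C); missingness is MCAR, matching the
imputation the sampler performs.  `preset_london_like()` mirrors the
reference scale (1461 days, 12 correlated metrics, group weights
0.79/0.04/0.17, 21.6 deaths/day, risks 0.98/1.00/1.02, 5% missingness — the
true missingness fraction of the original record is not reported, so 5% is
a package choice).  `preset_recovery()` boosts the risks to ±0.3 on the log
scale so that desk-scale chains have power; `preset_null()` is a one-group
control.  What the generator does *not* emulate: instrument artefacts,
spatial heterogeneity across sites, source-apportionment structure,
day-of-week or influenza cycles, and missingness that is informative.
Passing tests on these data therefore demonstrate correctness of the
machinery, not robustness to every feature of real monitoring data.

## Numerical choices and degenerate inputs

Stick values are clamped to `[1e-12, 1 - 1e-12]` before weights are formed;
Cholesky factorisations of cluster precisions retry once with a `1e-8`
jitter; conditional-imputation covariances get a `1e-12` ridge; a
constant-valued trace is flagged rather than crashing the ESS computation;
a zero-MAD exposure column, an all-zero outcome (undefined offset), a
duplicate date and a lag at least as long as the series are all explicit
errors.  PAM is deterministic given `S`, so reruns with one seed reproduce
every output byte-for-byte.

## Known limitations

* `sigma_eps` is weakly identified from daily counts around 20: with the
  Gamma(5, 0.5) prior its posterior settles well above a small true value
  (0.13 vs 0.05 in the recovery benchmark).  Partition recovery and
  relative risks are unaffected, but `sigma_eps` itself should be read as
  prior-sensitive.
* The label-move acceptance rate is low (< 1%) when clusters are genuinely
  well separated; that is expected — the moves matter exactly when the
  posterior is (near-)symmetric.
* Representative-partition selection searches `k >= 2`; a truly
  one-cluster posterior appears as one dominant cluster plus a small
  splinter rather than `k = 1`.
* Scenario prediction assumes the training normalisation and covariate
  model still describe the scenario days; structural change in the mixture
  (new sources, instrument changes) is outside the model.
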