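---
title: "Multitrait Bayesian variable selection for correlated exposures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitrait Bayesian variable selection for correlated exposures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chemical exposures measured in human matrices — here, pollutant
concentrations in hair, in pg/mg — are numerous, strongly correlated within
chemical families, left-censored at per-compound limits of detection (LOD),
and partially missing for technical reasons. Cardiometabolic health is
itself multidimensional: adiposity (BMI, waist circumference), lipids
(triglycerides, total/HDL/LDL cholesterol), blood pressure (systolic,
diastolic) and glycaemia (fasting glucose) are correlated outcomes that
co-occur in the same individuals. Regressing each trait on each exposure
one pair at a time smears any true signal across all the correlated proxies
of the causal exposure, and multiplies the number of tests. **mtess**
implements the alternative: a single multivariate Bayesian variable
selection (BVS) model over the whole exposure panel and a set of jointly
modelled traits, surrounded by the supporting stages such an analysis
needs — network-guided outcome selection, censoring-aware preprocessing,
and permutation-calibrated decision rules.

## The selection model

Let `Y` be the `n x q` matrix of traits and `X` the `n x p` matrix of
log10 exposures, both residualized on the adjustment covariates (age,
gender, education, smoking, diet PCA scores) and standardized. A binary
vector `gamma` selects predictor columns. Conditional on `gamma`, the model
is a multivariate regression with a conjugate matrix-variate g-prior on the
included coefficients — row covariance `g (X_g' X_g)^{-1}`, column
covariance equal to the residual covariance `Sigma` — and a Jeffreys prior
on `Sigma`. Integrating out coefficients and `Sigma` gives the marginal
likelihood, up to a `gamma`-free constant,

```
log m(gamma) = -(q k / 2) log(1 + g) - (nu / 2) log det( Y'Y - g/(1+g) Y' P_gamma Y )
```

where `k` is the model size, `P_gamma` the projector onto the span of the
included columns, `nu` the residual degrees of freedom (`n - 1` minus the
covariate rank adjustment), and `g = n` by default (unit information). The
same covariance-aware score underpins all multitrait results: a predictor
is rewarded for explaining the *joint* trait structure, not any single
outcome.

Covariate adjustment is by residualization of both `Y` and `X`. Under the
conjugate prior this is equivalent to forcing the covariates into every
model, up to degrees-of-freedom corrections, which the `nu` argument makes
explicit.

### Prior on model size

Sparsity comes from a beta-binomial prior on `k` whose two hyperparameters
are moment-matched to a prior expected model size `E = 5` and standard
deviation `S = 4`, truncated at `T = min(p, E + F S)` with `F = 7` and
renormalized; each model of size `k` then gets prior `pmf(k) / choose(p, k)`.
For `p = 33` this gives `a = 1.60`, `b = 8.95`, `T = 33` and places
probability 0.972 on sizes up to 14. When `S^2` is infeasible for a
beta-binomial on `p` trials (either below the binomial variance or above
the maximum at `a + b -> 0`), the prior falls back to a binomial with the
same mean, with a warning.

### The sampler

The posterior over `2^p` models is explored by an evolutionary stochastic
search MCMC with parallel tempering: three chains at temperatures
`1, r, r^2` run jointly. Each sweep applies, per chain, one
Metropolis-Hastings mutation (add a predictor with probability 0.45, delete
with 0.45, swap with 0.10, with the exact proposal-ratio correction for the
add/delete asymmetry); with probability 0.33 one uniform crossover between
two random chains, accepted jointly at their temperatures; and one state
exchange between a random adjacent-temperature pair. The ladder ratio `r`
starts at 1.3 and is adapted every 100 burn-in sweeps toward a 0.5 exchange
acceptance rate (multiplicative update on `r - 1`, clamped to
`[1.001, 8]`), then frozen. Only the cold chain after burn-in is recorded.
Default run lengths are 30,000 sweeps with 10,000 burn-in.

The sweep loop and marginal-likelihood kernel are implemented in C++
(RcppArmadillo) from precomputed cross-products `X'X`, `X'Y`, `Y'Y`, so a
sweep costs `O(k^3 + k^2 q)` independent of `n`. All randomness flows
through R's RNG: a seed fixes the entire run bitwise.

For panels with `p <= 15` the package also enumerates the exact posterior
(`enumerate_posterior()`); the test suite verifies that sampler visit
frequencies converge to it in total variation (< 0.05 at the default run
length) and that the marginal-likelihood kernel agrees with an independent
QR-based implementation to 1e-8.

## Posterior summaries and decisions

* **MPP** — a model's visit frequency among post-burn-in cold-chain sweeps;
  ties in the best-models-visited ranking are broken lexicographically on
  the sorted predictor-name key so reports are reproducible.
* **MPPI** — per-feature sum of MPP over models containing it.
* **Empirical FDR threshold** — the sampler is rerun on row-permuted `Y`
  (rows permuted jointly across traits, preserving their correlation under
  the null; `X` fixed). For a candidate threshold `t`, the estimated FDR is
  the expected permutation exceedance count divided by the observed
  exceedance count, with a pseudocount of one permutation exceedance in the
  numerator — the standard guard against certifying a zero false-discovery
  rate from finitely many permutations. Without the pseudocount a single
  permutation exceedance among the default 20 runs sits exactly at the 0.05
  boundary and the realized null family-discovery rate roughly doubles
  (~10% instead of ~4-5% in the package's null calibration suite). `t*` is
  the smallest observed MPPI with estimated FDR at or below the level; if
  none qualifies the significant set is empty and `t*` is the sentinel
  `Inf`.
* **BF and RBF** — a feature's Bayes factor is its posterior-to-prior odds
  of inclusion, `BF = [m/(1-m)] / [pi0/(1-pi0)]` with `pi0 = E/p`; MPPIs
  are capped at `1 - 1/n_kept` (one post-burn-in sweep of resolution) so
  always-included features stay finite. The ratio of Bayes factors divides
  by the BF of a hypothetical feature sitting exactly at `t*`, so RBF = 1
  marks the significance boundary and RBF is comparable across models with
  different outcomes. With the sentinel `t*` the reference switches to the
  maximum observed MPPI and the result is flagged.
* **Effect sizes** — conditional on a model (by default the top BMV), the
  conjugate posterior factorizes as inverse-Wishart for `Sigma` (scale
  `Y'Y - g/(1+g) Y'P Y`, `nu` degrees of freedom) and matrix-Gaussian for
  the coefficients given `Sigma` (mean `g/(1+g)` times least squares). Each
  round draws 2 covariance samples and 2 coefficient matrices per
  covariance — the classical 2 x 2 inner structure — over 500 rounds by
  default (2,000 draws per coefficient). A sign is called when the
  25th-75th percentile interval excludes zero. Whether such simulation
  should condition on the single top model or average over retained sweeps
  is an open choice; conditioning on the top BMV is the default because it
  matches how the top model is reported, and any visited model can be
  passed instead.

## Stability-calibrated networks

Outcome selection (which traits to model jointly) and exposure-block
exploration use conditional-independence networks estimated by the
graphical LASSO (blockwise coordinate descent, penalized Gaussian
log-likelihood, entrywise penalty matrix) on `K = 100` subsamples of 50% of
the participants. For each penalty `lambda` on a 20-point log grid — from
the smallest penalty that empties the full-data graph down to 1% of it —
each edge gets a selection count `u_e` out of `K`.

Given a selection-proportion threshold `pi`, edges split into stably
selected (`u_e >= ceil(K pi)`), stably excluded (`u_e <= floor(K(1-pi))`)
and unstable. Under the instability null all edges are exchangeable with
pooled selection probability `mu = sum(u_e)/(K N)` and
`u_e ~ Binomial(K, mu)` i.i.d. The stability score is the negative log
null-probability of the *confidently classified* edges. Two design choices
deserve explanation:

* **Unstable edges contribute nothing to the score.** Including their
  `-log P(unstable)` term makes the score degenerate: near the empty end of
  the penalty grid a single borderline edge (selection proportion near 0.5
  while the pooled mean is near 0) is astronomically improbable under the
  null, so the "most stable" configuration would be one with zero stable
  edges. Only the stably selected and stably excluded categories carry
  stability evidence; with that convention an all-`K/2` configuration
  scores 0, separation strictly increases the score, and fully separated
  0/1 proportions are maximal at fixed `mu`.
* **Discoveries must exceed their own error bound.** The expected number of
  falsely selected edges is bounded by `q^2 / ((2 pi - 1) N)` (the
  stability-selection per-family error rate, PFER, with `q` the average
  number of selected edges per subsample). Calibration maximizes the score
  over the `(lambda, pi)` grid subject to the bound staying below the
  network budget (10 for the trait network, 20 for the exposure network),
  *and* subject to the stable-edge count strictly exceeding the bound —
  a configuration whose discoveries could all be false carries no evidence.
  Without the second condition a signal-free block maximizes its score on
  noise inside its PFER allowance; with it, null blocks correctly return
  empty edge sets.

In multiblock mode (diet + chemicals) every block-pair — within-1,
within-2, between — is calibrated by its own score over the shared
subsample fits, and the network PFER budget is apportioned to block-pairs
by their share of candidate edges, so the summed bound respects the
network-wide constraint. Communities of the stable graph are found with
the Louvain algorithm at unit edge weights and resolution 1. Traits with
degree at least 2 in the calibrated trait network form the multivariate
outcome of the main analysis.

One caveat: a small, densely correlated block (such as the five dietary
intakes) has a large `q` whenever anything is selected, so its PFER share
can be unsatisfiable and the block may legitimately calibrate to an empty
edge set. That is a property of error-controlled stability selection on
dense blocks, not a failure of the search.

## Preprocessing

* **Exclusions.** Participants with no valid exposure panel at all are
  excluded first, then those missing at least half of the dietary items;
  the exclusion log preserves `initial = retained + sum(excluded)` by
  construction. Per-compound technical missingness below 50% is imputed,
  not excluded.
* **Below-LOD imputation.** Censored entries are drawn from a Gaussian
  truncated to `(0, LOD)` by inverse-CDF sampling. The Gaussian's location
  and scale are fitted per compound by censored maximum likelihood on the
  natural concentration scale (observed values plus the censored count);
  with fewer than 10 observed values the fallback is `mu = LOD/2`,
  `sd = LOD/4`. Whether to fit per compound or use fixed parameters is
  configurable because assay practice varies.
* **Missing data.** Round-robin iterative conditional imputation, most
  complete columns first: numeric columns use a linear-model learner with
  predictions clamped to the observed range (no extrapolation below a
  concentration floor), categorical columns a classification tree;
  iteration stops when the relative change of imputed values drops below
  1e-3 or after 10 sweeps. A linear learner is used for numeric columns
  because imputation here must respect near-linear relations between
  intake variables and between correlated traits exactly.
* **Diet PCA.** The five intake variables are standardized and summarized
  by as many principal components as needed to pass 95% cumulative
  variance; with the default synthetic diet correlation that is three
  components, matching the structure of food-frequency data where energy
  tracks the macronutrients and fibre adds a partly independent axis.

## The synthetic cohort generator

There is no public individual-level dataset for this design, so the
generator is a first-class module: every downstream stage is exercised on
cohorts whose generating truth is known and recorded.

* Exposures: a Gaussian copula on the log10 scale with family-block latent
  correlation (0.5 within, 0.1 between by default, across the 33-compound
  panel of PCBs, organochlorines, organophosphates, pyrethroids and other
  pesticide classes); per-compound LODs are placed at the
  `1 - detection_target` quantile of the generating log-normal (default
  detection 0.7, configurable per compound; the 0.10 floor mirrors the
  usual inclusion criterion), below-LOD values are flagged rather than
  replaced, and an MCAR mask adds technical missingness.
* Covariates and diet: age N(44.8, 13.5^2) years, 69% female,
  low/intermediate/high education and never/former/current smoking at
  realistic frequencies, and five positive intake variables with
  corr(energy, fat) = 0.88 and a near-rank-3 correlation structure.
* Traits: a sparse standardized effect matrix on standardized log
  exposures plus correlated Gaussian residuals (BMI-WC 0.89, TC-LDL 0.90,
  SBP-DBP 0.76, WC-FPG 0.51 among the defaults). Pearson correlations on
  the Gaussian residual scale stand in for the Spearman values reported for
  real cohorts; for monotone-transformed Gaussians the two are close.
* For network tests, `generate_graph_gaussian()` plants an exact
  conditional-independence graph via a diagonally dominated precision
  matrix.

What the generator does *not* emulate: hair growth and segmental assay
kinetics, measurement error beyond censoring, covariate-exposure
confounding (exposures are drawn independently of covariates by default),
non-Gaussian trait margins, and outcome-dependent missingness. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated generating assumptions, not robustness to everything real data
can do.

## Numerical choices and degenerate inputs

* Positive definiteness of every generated correlation/covariance matrix is
  asserted (minimum eigenvalue > 1e-10) before any sampling.
* Graphical-LASSO convergence: mean absolute off-diagonal change below
  1e-4 of the mean absolute covariance, inner coordinate descent to 1e-6,
  at most 100/200 iterations; edges are nonzero precision entries above
  1e-8.
* Rank-deficient model proposals get marginal likelihood `-Inf` (rejected,
  never raised); residualization rejects predictors whose post-projection
  variance falls below 1e-10, by name.
* Truncated-Gaussian draws clamp to the open interval; a fitted Gaussian
  with essentially no mass in `(0, LOD)` falls back to a flat draw over the
  interval.
* `run_guess`, `generate_*`, `impute_*`, `calibrate_network` and
  `run_pipeline` are bitwise deterministic given their seed.

## Problem sizes used by the test and acceptance suites

The suites run everything at desk scale, chosen so the full test run stays
in the low minutes while estimates remain well inside their tolerance
bands: exact-vs-sampler comparisons at `p = 6, q = 2, n = 50` with 30,000
sweeps; planted-signal recovery at `n = 500, p = 33` with 10,000 sweeps and
10 replicates; null FDR calibration over 50 simulations at
`p = 12, n = 200`, 3,000 sweeps and 20 permutations; network recovery at
`n = 941` with `K = 100` subsamples. The analysis scripts under `analysis/`
run the full-scale settings (941 participants, 30,000 sweeps, `K = 100`).

## Known limitations

* The stability score is a reconstruction from its published description;
  its exact published form (and the block-specific variant) may differ in
  normalization, so calibrated `(lambda, pi)` values are comparable within
  this package, not across implementations.
* The sampler records only the cold chain; MPP for models never visited is
  zero by construction, so Bayes factors are resolution-limited at
  `1/n_kept`.
* The permutation-FDR procedure reruns the full sampler per permutation;
  with few permutations the threshold is coarse. Defaults use 20
  permutations; raise them for reporting-grade thresholds.
* Binary or survival outcomes, interaction terms and nonlinear dose
  response are out of scope.
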