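# ipssirt

Pharmacometric item-response-theory (IRT) analysis of the International
Prostate Symptom Score (IPSS) for benign prostatic hyperplasia (BPH) trials.

The IPSS sums seven 0–5 items into a 0–35 total. Summing loses information:
items differ in how sharply they discriminate disease severity, and the same
total can hide different symptom profiles. `ipssirt` is for
pharmacometricians and trial statisticians who want to analyze the item-level
data instead: it estimates how each item maps onto an underlying latent
disability, models the time course of that disability in a
placebo-controlled trial, and quantifies what the item-level approach buys in
power to detect a drug effect.

## What it implements

* **Graded response model (GRM).** Cumulative item response curves
  `P(Y_ij >= k) = plogis(a_j (psi_i - b_jk))`, category probabilities,
  expected scores, Fisher information, and response-pattern likelihoods, in
  one latent dimension or two (voiding items 1, 3, 5, 6 / storage items
  2, 4, 7).
* **ICC estimation under the IDVIS scheme.** Marginal maximum likelihood
  treating every patient-visit as an independent pseudo-individual, latent
  disability fixed N(0, 1) at baseline with an estimated post-baseline
  mean/variance shift (44 fixed effects unidimensional, 47 bidimensional
  with an inter-dimension correlation); empirical Bayes disability estimates
  with curvature standard errors and shrinkage summaries.
* **Fisher-information ranking** of the items over a disability range, with
  a built-in range-sensitivity sweep.
* **Longitudinal mixed-effects models** for total IPSS and latent
  disability: `Baseline + Pmax(1 - exp(-(ln2/Tprog t)^WEI)) + Drift t +
  Drug`, log-normal/normal/Box-Cox random effects, stepwise covariate
  search, the sequential PSI-IPPSE stage (EBE standard errors as a known
  residual component), and the joint item-level model with fixed or
  re-estimated ICCs — all by vectorized per-subject Laplace marginalization.
* **Diagnostics.** An eta-sampling GAM check of the ICCs that is robust to
  EBE shrinkage (posterior draws, GCV cubic-spline smooths, bands widened by
  sqrt(n_samples)), residual item correlations, and visual predictive
  checks.
* **Power engine.** Stochastic simulation and estimation with empirically
  calibrated likelihood-ratio thresholds, against cross-sectional and
  while-on-treatment ANCOVA benchmarks.
* **Trial simulator.** Synthetic four-arm, 403-patient, 6-month dose-finding
  trials (screening inclusion IPSS >= 13, baseline covariates, optional
  missingness/dropout), with the published parameter estimates shipped as
  the default simulation truth (`reference_item_bank()`,
  `reference_longitudinal()`).

## Worked example

```r
library(ipssirt)

# simulate the measurement design and refit the item model
dat <- simulate_idvis_dataset(reference_item_bank("unidimensional"),
                              reference_latent_shift("unidimensional"),
                              n_patients = 403, seed = 1)
fit <- fit_icc(dat, n_dimensions = 1)
fit
#> IDVIS graded-response ICC fit (1-dimensional): 3224 pseudo-individuals
#>   44 fixed effects, OFV = 66603.74, AIC = 66691.74, converged: TRUE
#> Graded-response item bank: 7 items, 1 latent dimension
#>  item dimension      a   tau1   tau2     tau3   tau4  tau5
#>     1   general 1.4695 -3.821 -2.154 -0.50131 0.8300 2.101
#>     2   general 1.0272 -4.995 -2.594 -0.66201 0.8252 2.296
#>     3   general 1.4160 -3.500 -1.830 -0.32813 0.6979 1.846
#>     4   general 0.9255 -3.718 -1.681 -0.01321 1.2143 2.704
#>     5   general 1.1078 -4.962 -2.643 -0.99024 0.3089 1.373
#>     6   general 0.9599 -2.917 -1.257  0.39476 1.9635 3.600
#>     7   general 0.5291 -7.412 -2.454  0.85664 3.1601 5.142
#> Post-baseline shift: mean -1.267 ; variance 2.206

ebe <- disability_estimates(fit, dat)
cor(dat$total, ebe$ebe)^2
#> [1] 0.9631313

information_share(fit$bank, range(ebe$ebe))
#> Fisher information shares over disability range [-5.03, 3.13]
#>  item               label subscore    auc share cumulative
#>     1 incomplete emptying  voiding 4.6630  24.7       24.7
#>     3       intermittency  voiding 4.2370  22.4       47.1
#>     5         weak stream  voiding 2.7330  14.5       61.5
#>     2           frequency  storage 2.4800  13.1       74.6
#>     6           straining  voiding 2.0820  11.0       85.7
#>     4             urgency  storage 2.0320  10.8       96.4
#>     7            nocturia  storage 0.6787   3.6      100.0
```

The fit recovers the reference item parameters from 3,224 simulated
pseudo-individuals; the squared correlation of ~0.96 says the total score
tracks latent disability closely but not perfectly, and the ranking shows
the four voiding items carrying ~72% of the measurement information, with
nocturia nearly uninformative (3.7%).

Longitudinal stage and power, at production scale:

```r
trial <- simulate_trial(trial_design(seed = 1), simulation_truth())
eb    <- disability_estimates(fit, trial)
fp    <- fit_psi_ippse(eb, trial)        # sequential latent-disability fit
pw    <- sse_power(n_reps = 1000)        # SSE power curves (long-running)
```

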