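---
title: "Item response theory and longitudinal modelling of the IPSS: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Item response theory and longitudinal modelling of the IPSS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The International Prostate Symptom Score (IPSS) summarizes seven lower-urinary-tract symptoms, each scored 0–5, into a total of 0–35. Summing discards information: two patients with the same total can have very different symptom profiles, and the seven items are not equally sensitive to the underlying disease severity. `ipssirt` treats the item scores as ordered-categorical measurements of a latent *disability* and models them with Samejima's graded response model (GRM):

$$P(Y_{ij} \ge k) = \frac{e^{a_j(\psi_i - b_{j,k})}}{1 + e^{a_j(\psi_i - b_{j,k})}},
\qquad P(Y_{ij} = k) = P(Y_{ij} \ge k) - P(Y_{ij} \ge k+1),$$

with item discrimination $a_j > 0$, ordered thresholds $b_{j,1} < \dots < b_{j,5}$, and no logistic scaling constant ($D = 1$). Higher $\psi$ means greater disability. The package couples this measurement model with nonlinear mixed-effects models for the time course of disability (and, in parallel, of the observed total score) in a placebo-controlled dose-finding trial, and with a simulation-based power engine.

## Threshold parameterization

Published difficulty tables for this questionnaire report, per item, one negative location followed by four values that are not monotone. Read as absolute thresholds they would produce negative category probabilities; read as the first threshold plus positive increments they give strictly ordered thresholds for all seven items. `ipssirt` adopts the increment reading: `thresholds_from_increments()` converts the reported vector by cumulative summation, estimation parameterizes increments on the log scale (so ordering can never be violated), and all reporting prints both forms. This interpretation is an assumption of the package, made because the alternative is mathematically inadmissible.

## ICC estimation under the independent-visit (IDVIS) scheme

Item characteristic curves are estimated by marginal maximum likelihood with every patient-visit treated as an independent pseudo-individual. The latent variable is fixed to a standard normal at baseline; post-baseline visits share one estimated mean and variance per dimension (and, with two dimensions, one correlation shared between origins, estimated through a Cholesky factor). A full fit therefore has 44 fixed effects in one dimension (35 difficulties, 7 discriminations, 2 shift parameters) and 47 in two.

Numerical choices:

* **Integration.** Gauss–Hermite quadrature anchored at the per-origin prior, 41 nodes per dimension in one dimension and a 13 × 13 tensor grid pushed through the prior Cholesky in two. An adaptive variant centred at each pseudo-individual's posterior mode is available (`icc_ofv(..., method = "agh")`); on test fixtures 21 adaptive nodes agree with 101 fixed nodes to well under 0.01 OFV units.
* **Optimization.** Bock–Aitkin EM: the expected complete-data item objectives are maximized by a few BFGS steps with analytic gradients (discrimination and increments on the log scale), and the shift parameters are updated from posterior moments. Iteration stops when the OFV changes by less than 0.01 (absolute; the OFV at the full design is of order 10^4^, so this is a relative change below 10^-6^). The EM map is monotone for fixed grids, which in practice removes the need for multi-start safeguards; starting values come from inverse-logit transforms of pooled cumulative frequencies, which is deterministic, so a fit is exactly reproducible.
* **Standard errors.** Finite-difference Hessian of the quadrature OFV on the transformed scale, mapped back by the delta method.
* **Missing items** are dropped from the likelihood (missing at random).
* **Degenerate inputs.** Data with only baseline rows leave the shift non-identified; the fit flags this rather than failing. An all-constant item drives its discrimination to the boundary and is reported as such.

Empirical Bayes estimates (EBEs) of disability maximize the response log-likelihood plus the origin's log prior, by damped Newton with analytic derivatives (the GRM likelihood is log-concave in $\psi$) and a fine grid fallback; the standard error is the curvature at the mode. SD-based shrinkage is reported overall and per pseudo-individual.

## Fisher information

Item information is $\sum_k (\partial P_k/\partial\psi)^2 / P_k$. Rankings integrate each item's curve by the trapezoid rule on a 2,001-point grid over a disability range. The range the original analysis used is not recoverable, so the default is the empirical range of the fitted EBEs and `information_sensitivity()` always sweeps fixed alternatives ([−4, 4], [−6, 3]); in all of these the ranking is stable (incomplete emptying first, nocturia last, voiding items ≈ 72% of the total). Exact percentage reproduction is not attempted because of the unknown range. Information ranking is restricted to unidimensional banks: across two latent scales the item informations are not commensurable.

## Longitudinal models

Both observed total IPSS and latent disability follow

$$\text{IPSS or Disability} = \text{Baseline} + \text{Placebo}(t) + \text{Drug}, \qquad
\text{Placebo}(t) = P_{max}\left(1 - e^{-\left(\frac{\ln 2}{T_{prog}} t\right)^{WEI}}\right) + \text{Drift}\cdot t,$$

with time in months, an offset drug effect switched on at post-dose visits of active arms (a dose-independent present/absent effect), the typical drift fixed to zero, and $WEI = 1$ (exponential) except in the bidimensional model, where a common Weibull exponent is estimated. Inter-individual variability is log-normal on Baseline~IPSS~ and T~prog~, normal on P~max~, Drift and the latent-scale Baseline, with optional Box-Cox transformation of the Baseline and Drift effects, $\eta^* = ((e^{\eta})^{\lambda} - 1)/\lambda$. The drug effect carries no IIV by default (it was inestimable against the placebo-response variability in the motivating data). Residual-error assignment: the combined proportional + additive model belongs to the total-score fit; the latent-scale models use an additive term only, because a proportional error on a variable centred near zero is ill-defined.

Three fits share one estimation engine (`fit_total_score()`, `fit_psi_ippse()`, `fit_joint()`): per-subject Laplace marginalization with the inner Newton solve vectorized across subjects (batched Cholesky factorizations), conditional-likelihood derivatives with respect to the random effects by central finite differences, and quasi-Newton outer optimization with wide central-difference gradients (the warm-started inner solve leaves sub-1e-5 noise on the objective that defeats machine-step differencing). A subject's penalized likelihood can be multimodal (saturating placebo curves with log-normal half-life effects), so the inner solve warm-starts from the previous modes for continuity but checks every mode against the value at $\eta = 0$: a mode provably worse than the zero point means the warm start tracked a dead basin, and that subject is re-solved from zero. Premature stops are restarted from the terminal point; a restart that improves the OFV by less than 0.01 counts as converged. Full/reduced test pairs warm-start the full model at the reduced optimum (the extra effect starting at zero), which guarantees a nonnegative OFV difference; covariate-search candidates warm-start from the incumbent model the same way. With weakly identified pairs — a placebo half-life beyond the observation window makes ($P_{max}, T_{prog}$) a ridge — the individual parameters wander along the ridge while Baseline and Drug, the quantities of scientific interest, stay well determined; this mirrors the large standard errors reported for placebo parameters in the motivating analysis.

The **PSI-IPPSE** stage models the per-visit disability EBEs with per-observation residual variance $se_i^2 + \sigma_{add}^2$, so estimation uncertainty from the measurement stage propagates into the longitudinal fit; $\sigma_{add}$ absorbs any residual misfit and may legitimately go to zero. The **joint** model replaces the EBE plug-in with the full item-level likelihood; by default the ICCs stay fixed at the measurement-stage estimates (re-estimating them jointly is supported but, as in the motivating analysis, changes the fit only marginally on well-specified data). Joint fits take their starting values from the sequential stage.

**Covariates** enter multiplicatively, $\theta(1 + \theta_{cov}(c - \tilde c))$, except on parameters whose typical value can be zero (latent baseline), which use the additive form; centering is at the sample median. `covariate_search()` performs greedy forward inclusion at p < 0.01 (ΔOFV > 6.635, df 1) and backward elimination at p < 0.001 (ΔOFV > 10.828).

## Diagnostics

The η-sampling GAM check addresses a real failure mode of EBE-based smooths: shrinkage drags estimates toward the prior mean and can make a correct model look wrong at the extremes. For each pseudo-individual, 200 disability values are drawn from N(EBE, SE²) — the draws inherit the baseline/post-baseline origin because both moments were computed under that origin's prior — and a GCV-selected cubic-spline smooth (basis dimension 10) of each cumulative score indicator is compared against the model curve. Since each real observation appears `n_samples` times, the smooth's standard error is multiplied by √`n_samples` before the ±1.96 expansion (multiplying before or after is algebraically identical). A panel is flagged when the model curve leaves the adjusted band on more than 10% of the grid.

Residual item correlations (observed minus expected score at the EBE) screen for local-independence violations. VPCs compare observed 5th/50th/95th percentiles per nominal visit with simulation-based 95% intervals (200 replicates for summary-score models, 2,000 for item-level models, by convention); binning is at nominal visit times because the design is balanced.

## Trial simulator

The generator reproduces the design features the analysis relies on: 403 patients in four arms (placebo, 10, 20, 30 mg) at 1:1:1:1 allocation (the observed 98/101/99/105 split is available as a preset), visits at 0, 0.5, 1, …, 6 months, screening inclusion at total IPSS ≥ 13, and baseline covariates (quality-of-life score, BPH Impact Index, region) with discrete distributions matched to the published baseline table (QoL median 4, BII median 7, ≈ 60% North America). Screening is simulated as a separate response vector at the baseline latent value plus an independent N(0, 0.3²) perturbation, with rejection sampling applied at screening only — observed baseline totals may legitimately fall below 13, as in the real trial. Item missingness and dropout default to zero (the power analysis assumes complete data) but are configurable. Per-patient random streams are derived deterministically from the design seed, so enlarging a trial never reshuffles existing patients.

Two features of real data the generator does not emulate: response styles / informative missingness (the observed item-count bookkeeping in the motivating data implies a small, unexplained number of incomplete questionnaires — the generator exposes a generic missingness rate instead), and any dose–response shape (the reference truth has a single dose-independent drug effect, as selected in the motivating analysis). Passing recovery tests therefore demonstrates internal consistency of estimator and simulator under the published parameter values, not robustness to these unmodelled features.

## Power engine

`sse_power()` implements stochastic simulation and estimation: item-level trials are simulated from the bidimensional longitudinal IRT truth (the lowest-AIC model), then analyzed by full/reduced likelihood-ratio tests in the bidimensional (df 2 — two drug parameters), unidimensional and total-score models, and by two ANCOVAs of change from baseline on treatment plus baseline total — cross-sectional at the 3-month landmark, and the "while on treatment" average over all post-baseline visits. The ANCOVA treatment term is pooled active-vs-placebo by default (the simulation truth has one dose-independent effect); a four-level-factor F-test variant is available. Model-based tests use empirically calibrated thresholds: the 95th percentile of ΔOFV across replicates simulated with the drug effect set to zero, per sample size and estimation model, rather than the nominal 3.84. Only replicates in which both members of a full/reduced pair converged are counted; 80%-power sample sizes come from isotonic-then-linear interpolation over the n grid. Replicate seeds are derived from the master seed, so results are independent of evaluation order.

Scale: production use is 1,000 replicates (plus 1,000 null replicates) at n ∈ {33, 66, 99, 137}, which is a cluster-sized computation with the model-based methods. The test suite exercises the machinery at one sample size with tens of replicates and the total-score model, where the qualitative contrast against cross-sectional ANCOVA is already decisive, and verifies the threshold calibration against its χ²(1) limit on a linear-Gaussian toy model.

## Known limitations

* Laplace marginalization (like any first-order method) can bias variance components when per-subject information is sparse; OFV values are comparable within this package but not across marginalization schemes.
* The bidimensional ICC shift update uses posterior-moment steps for the correlation; on small datasets a final OFV comparison against the unidimensional fit is the recommended check (the nesting invariant is part of the test suite).
* Recovery of ($P_{max}, T_{prog}$) individually is poor by construction when the placebo half-life exceeds the trial duration; inferences should focus on Baseline, Drug and the placebo trajectory as a function.
* The empirical-threshold calibration makes each method's type-I error 5% *by construction on the null replicates*; with few replicates the threshold itself is noisy, which is why the calibration warns below 100 null replicates.

## Reproducing the headline quantities

```{r}
library(ipssirt)

# measurement stage at the full design
dat <- simulate_idvis_dataset(reference_item_bank("unidimensional"),
                              reference_latent_shift("unidimensional"),
                              n_patients = 403, seed = 1)
fit <- fit_icc(dat, n_dimensions = 1)
ebe <- disability_estimates(fit, dat)
cor(dat$total, ebe$ebe)^2            # ~0.95: total score vs disability

information_share(fit$bank, range(ebe$ebe))   # item ranking

# longitudinal stage and power (production scale; see text)
trial <- simulate_trial(trial_design(seed = 1), simulation_truth())
fp <- fit_psi_ippse(ebe = disability_estimates(fit, trial), dataset = trial)
pw <- sse_power(n_reps = 1000)
```
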