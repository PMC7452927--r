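# Structural placebo/drug models, Box-Cox random effects, the Laplace
# engine, and the three longitudinal fit types at small scale.

test_that("placebo time-course hits its landmarks", {
  expect_equal(placebo_response(0, -4, 10), 0)
  expect_equal(placebo_response(10, -4, 10), -2)          # half-life
  # Weibull shape bends the half-life fraction
  wei <- 1.53
  expect_equal(placebo_response(10, -4, 10, wei = wei),
               -4 * (1 - exp(-log(2)^wei)), tolerance = 1e-12)
  expect_equal(-4 * (1 - exp(-log(2)^1.53)) / -4, 0.435, tolerance = 0.001)
  expect_equal(placebo_response(2, 0, 5, drift = 0.3), 0.6)
  expect_error(placebo_response(-1, -4, 10), "nonnegative")
  expect_error(placebo_response(1, -4, 0), "positive")
})

test_that("structural prediction adds the drug offset on active arms only", {
  p <- c(baseline = 19.6, pmax = -4.12, tprog = 15.3, drug = -1.98)
  expect_equal(structural_prediction(p, "placebo", 1e9), 19.6 - 4.12,
               tolerance = 1e-9)
  expect_equal(structural_prediction(p, "30mg", 1e9), 19.6 - 4.12 - 1.98,
               tolerance = 1e-9)
  expect_equal(structural_prediction(p, "20mg", 0), 19.6)
  expect_error(structural_prediction(p, NA, 1), "arm")
  # continuity in t near 0 (drug switches on for t > 0 only)
  expect_equal(structural_prediction(p, "placebo", 1e-9), 19.6,
               tolerance = 1e-6)
})

test_that("the Box-Cox transform has the documented limits", {
  expect_equal(boxcox_eta(0.5, 1e-12), 0.5)
  expect_equal(boxcox_eta(0, 1.87), 0)
  expect_equal(boxcox_eta(1, 1.87), (exp(1.87) - 1) / 1.87,
               tolerance = 1e-12)
  expect_equal(boxcox_eta(1, 1.87), 2.935, tolerance = 0.001)
})

test_that("the Laplace engine reproduces a linear mixed model fit", {
  # random-intercept Gaussian model: Laplace is exact; lme4 ML is the oracle
  set.seed(88)
  n <- 60L; v <- 5L
  b <- rnorm(n, 0, 1.2)
  df <- data.frame(id = rep(seq_len(n), each = v),
                   y = 3 + rep(b, each = v) + rnorm(n * v, 0, 0.7))
  lmer_fit <- lme4::lmer(y ~ 1 + (1 | id), data = df, REML = FALSE)
  ends <- seq(v, n * v, by = v)
  cll <- function(theta, eta) {
    mu <- theta[1L] + eta[df$id, 1L]
    sdv <- exp(theta[2L])
    cs <- cumsum(-0.5 * ((df$y - mu) / sdv)^2 - log(sdv) -
                   0.5 * log(2 * pi))
    cs[ends] - c(0, cs[ends[-n]])
  }
  res <- ipssirt:::laplace_nlme(c(0, 0, 0), cll,
                                function(theta) matrix(exp(2 * theta[3L])),
                                n, 1L, lower = c(-Inf, -5, -5),
                                upper = c(Inf, 3, 3))
  expect_equal(res$ofv, -2 * as.numeric(logLik(lmer_fit)), tolerance = 1e-3)
  expect_equal(res$theta[1L], unname(lme4::fixef(lmer_fit)),
               tolerance = 1e-3)
  vc <- as.data.frame(lme4::VarCorr(lmer_fit))
  expect_equal(exp(res$theta[3L]), vc$sdcor[1L], tolerance = 1e-3)
  expect_equal(exp(res$theta[2L]), vc$sdcor[2L], tolerance = 1e-3)
})

test_that("total-score fit recovers a null drug effect and nests properly", {
  lg <- reference_longitudinal("ipss")
  lg$theta[["drug"]] <- 0
  lg$iiv$baseline$boxcox <- NULL; lg$iiv$drift$boxcox <- NULL
  lg$covariates <- lg$covariates[0, ]
  des <- trial_design(n_patients = 80L, visit_times = c(0, 1, 3, 6),
                      seed = 14L)
  dat <- simulate_total_score_trial(des, longitudinal = lg)
  red <- fit_total_score(dat, drug_effect = FALSE,
                         control = list(outer_iter = 80L))
  full <- fit_total_score(dat, drug_effect = TRUE, start = red,
                          control = list(outer_iter = 80L))
  expect_lt(abs(full$params$drug), 0.6)
  expect_lte(full$ofv, red$ofv + 0.1)       # nesting (allowing tiny noise)
})

test_that("PSI-IPPSE requires standard errors and uses them", {
  des <- trial_design(n_patients = 50L, visit_times = c(0, 1, 3, 6),
                      seed = 23L)
  dat <- simulate_trial(des, simulation_truth())
  f <- list(bank = uni_bank(), shift = uni_shift(), n_dimensions = 1L)
  class(f) <- "icc_fit"
  eb <- disability_estimates(f, dat)
  bad <- eb; bad$se[3L] <- NA
  expect_error(fit_psi_ippse(bad, dat), "standard errors")
  fit <- fit_psi_ippse(eb, dat, control = list(outer_iter = 60L))
  expect_true(is.finite(fit$ofv))
  expect_lt(fit$params$drug, 0.3)           # improvement direction
})

test_that("joint fit OFV is invariant to patient order and responds to the
          drug-effect nesting", {
  des <- trial_design(n_patients = 30L, visit_times = c(0, 1, 3, 6),
                      seed = 71L)
  dat <- simulate_trial(des, simulation_truth())
  ctl <- list(outer_iter = 40L, outer_rel_tol = 1e-6)
  f1 <- fit_joint(dat, uni_bank(), estimate_wei = FALSE, control = ctl)
  shuffled <- dat[sample.int(nrow(dat)), ]
  f2 <- fit_joint(shuffled, uni_bank(), estimate_wei = FALSE, control = ctl)
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-6)
  red <- fit_joint(dat, uni_bank(), drug_effect = FALSE,
                   estimate_wei = FALSE, control = ctl)
  expect_lte(f1$ofv, red$ofv + 0.1)
})

test_that("re-estimating ICCs on truth-simulated data changes the OFV only
          marginally", {
  des <- trial_design(n_patients = 30L, visit_times = c(0, 3, 6),
                      seed = 52L)
  dat <- simulate_trial(des, simulation_truth())
  ctl <- list(outer_iter = 12L, outer_rel_tol = 1e-5, restarts = 0L)
  fixed <- fit_joint(dat, uni_bank(), estimate_wei = FALSE, control = ctl)
  re <- fit_joint(dat, uni_bank(), re_estimate_icc = TRUE,
                  estimate_wei = FALSE,
                  start = fixed, control = ctl)
  dofv <- fixed$ofv - re$ofv
  expect_gte(dofv, -1)                       # extra parameters cannot hurt
  expect_lt(dofv, qchisq(0.95, 42L) * 2)     # no systematic misfit signal
})

test_that("covariate search keeps a real effect and drops pure noise", {
  lg <- reference_longitudinal("unidimensional")
  lg$covariates <- data.frame(parameter = "baseline", covariate = "qol_base",
                              form = "additive", coef = 0.325)
  tru <- simulation_truth(longitudinal = lg)
  des <- trial_design(n_patients = 120L, visit_times = c(0, 1, 3, 6),
                      seed = 61L)
  dat <- simulate_trial(des, tru)
  set.seed(62)
  dat$noise_cov <- rnorm(nrow(dat))[match(dat$patient_id,
                                          unique(dat$patient_id))]
  f <- list(bank = uni_bank(), shift = uni_shift(), n_dimensions = 1L)
  class(f) <- "icc_fit"
  eb <- disability_estimates(f, dat)
  fit_fn <- function(covs, start = NULL)
    fit_psi_ippse(eb, dat, covariates = covs, start = start,
                  control = list(outer_iter = 50L))
  cands <- data.frame(parameter = "baseline",
                      covariate = c("qol_base", "noise_cov"),
                      form = "additive")
  res <- covariate_search(fit_fn, cands)
  expect_true("qol_base" %in% res$covariates$covariate)
  expect_false("noise_cov" %in% res$covariates$covariate)
  # an empty candidate list returns the base fit unchanged
  base <- covariate_search(fit_fn, cands[0, ])
  expect_equal(nrow(base$covariates), 0L)
  expect_equal(nrow(base$trace), 0L)
})
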