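# Shared fixtures. Heavy full-design computations used by several
# acceptance checks are computed once per session and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

uni_bank <- function() reference_item_bank("unidimensional")
uni_shift <- function() reference_latent_shift("unidimensional")
bi_bank <- function() reference_item_bank("bidimensional")
bi_shift <- function() reference_latent_shift("bidimensional")

# Full trial design (403 patients x 8 visits) IDVIS simulation from the
# reference unidimensional ICC model, and its refit + disability estimates.
acc_idvis_data <- function() memo("acc_idvis_data",
  simulate_idvis_dataset(uni_bank(), uni_shift(), n_patients = 403L,
                         seed = 20260927L))

acc_icc_fit <- function() memo("acc_icc_fit",
  fit_icc(acc_idvis_data(), n_dimensions = 1L, se = FALSE))

acc_ebe <- function() memo("acc_ebe",
  disability_estimates(acc_icc_fit(), acc_idvis_data()))

# Small bidimensional IDVIS fixture for structure/nesting checks.
small_bi_data <- function() memo("small_bi_data",
  simulate_idvis_dataset(bi_bank(), bi_shift(), n_patients = 120L,
                         visit_times = c(0, 1, 3, 6), seed = 77L))

small_bi_fit <- function() memo("small_bi_fit",
  fit_icc(small_bi_data(), 2L, se = FALSE, max_iter = 150L))

# Well-specified unidimensional diagnostic fixture (true model as fit).
diag_fixture <- function() memo("diag_fixture", {
  d <- simulate_idvis_dataset(uni_bank(), uni_shift(), n_patients = 150L,
                              visit_times = c(0, 1, 3, 6), seed = 19L)
  f <- list(bank = uni_bank(), shift = uni_shift(), n_dimensions = 1L)
  class(f) <- "icc_fit"
  list(data = d, fit = f, ebe = disability_estimates(f, d))
})

# Total-score trial plus its fitted model, for VPC checks. The truth is
# the reference set without covariate effects or Box-Cox shapes, so the
# fitted model family contains the generative model and the
# calibration-under-truth property genuinely applies.
vpc_fixture <- function() memo("vpc_fixture", {
  lg <- reference_longitudinal("ipss")
  lg$iiv$baseline$boxcox <- NULL
  lg$iiv$drift$boxcox <- NULL
  lg$covariates <- lg$covariates[0, ]
  des <- trial_design(n_patients = 100L, seed = 33L)
  dat <- simulate_total_score_trial(des, longitudinal = lg)
  list(data = dat,
       fit = fit_total_score(dat, control = list(outer_iter = 60L)))
})

# A zero-IIV simulation truth for deterministic trajectory checks.
zero_iiv_truth <- function(model = "unidimensional") {
  lg <- reference_longitudinal(model)
  for (p in names(lg$iiv)) lg$iiv[[p]]$sd <- 0
  lg$correlations <- NULL
  lg$covariates <- lg$covariates[0, ]
  bank <- reference_item_bank(if (model == "ipss") "unidimensional" else model)
  simulation_truth(bank = bank, longitudinal = lg)
}
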