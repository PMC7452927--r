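# Trial simulator: design validation, reproducibility, screening,
# trajectories, item responses.

test_that("design validation enforces the invariants", {
  expect_error(trial_design(n_patients = 0), "at least one")
  arms <- data.frame(label = c("a", "b"), dose_mg = c(0, 10),
                     allocation = c(0.6, 0.6))
  expect_error(trial_design(arms = arms), "sum to 1")
  expect_error(trial_design(visit_times = c(1, 2)), "baseline")
  expect_error(trial_design(visit_times = c(0, 2, 2)), "increasing")
  expect_error(trial_design(dropout_rate = 1.5), "rates")
})

test_that("simulation is reproducible and stable in the patient index", {
  des <- trial_design(n_patients = 20L, visit_times = c(0, 1, 3), seed = 5L)
  tru <- simulation_truth()
  d1 <- simulate_trial(des, tru)
  d2 <- simulate_trial(des, tru)
  expect_identical(d1, d2)
  # growing the trial leaves the first patients' data unchanged
  des2 <- trial_design(n_patients = 25L, visit_times = c(0, 1, 3), seed = 5L)
  d3 <- simulate_trial(des2, tru)
  expect_equal(d3[d3$patient_id <= 20L, ], as.data.frame(d1),
               ignore_attr = TRUE)
})

test_that("arm allocation is randomized within binomial bounds", {
  des <- trial_design(n_patients = 403L, screening_threshold = -Inf,
                      seed = 12L)
  pop <- generate_population(des, simulation_truth())
  counts <- table(pop$arm)
  expect_equal(sum(counts), 403L)
  lo <- qbinom(0.005, 403L, 0.25)
  hi <- qbinom(0.995, 403L, 0.25)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("screening enforces a total score of at least 13 at screening", {
  des <- trial_design(n_patients = 60L, screening_threshold = 13,
                      visit_times = c(0, 3), seed = 9L)
  pop <- generate_population(des, simulation_truth())
  expect_true(all(pop$ipss_screen >= 13))
  # the rule binds at screening only: baseline totals may fall below it
  dat <- simulate_trial(des, simulation_truth())
  expect_true(any(dat$total[dat$time_months == 0] < 13))
})

test_that("trajectories follow baseline + placebo + drug", {
  tru <- zero_iiv_truth("unidimensional")
  des <- trial_design(n_patients = 8L, screening_threshold = -Inf, seed = 3L)
  pop <- generate_population(des, tru)
  # typical values at t = 0: baseline exactly
  tr0 <- generate_trajectories(pop, tru, 0)
  expect_equal(tr0$psi1, rep(0.0283, 8L), tolerance = 1e-12)
  # asymptote: baseline + pmax (+ drug on active arms)
  tr <- generate_trajectories(pop, tru, c(0, 1e6))
  far <- tr[tr$time_months > 0, ]
  act <- pop$dose_mg[match(far$patient_id, pop$patient_id)] > 0
  expect_equal(far$psi1[!act], rep(0.0283 - 1.03, sum(!act)),
               tolerance = 1e-6)
  expect_equal(far$psi1[act], rep(0.0283 - 1.03 - 0.542, sum(act)),
               tolerance = 1e-6)
  expect_error(generate_trajectories(pop, tru, c(-1, 0)), "negative")
})

test_that("a complete full design yields 22,568 item records", {
  d <- acc_idvis_data()
  expect_equal(nrow(d), 403L * 8L)
  expect_equal(sum(!is.na(as.matrix(d[paste0("item", 1:7)]))), 22568L)
  expect_true(all(d$total >= 0 & d$total <= 35))
  expect_equal(d$total,
               rowSums(as.matrix(d[paste0("item", 1:7)])))
})

test_that("item scores at very low disability are almost all zero except
          items with very low first thresholds", {
  tru <- zero_iiv_truth("unidimensional")
  des <- trial_design(n_patients = 40L, screening_threshold = -Inf,
                      visit_times = c(0, 1), seed = 8L)
  pop <- generate_population(des, tru)
  traj <- generate_trajectories(pop, tru, c(0, 1))
  traj$psi1 <- -10
  dat <- generate_item_responses(traj, tru$bank, des, pop)
  it <- as.matrix(dat[paste0("item", 1:7)])
  expect_true(mean(it[, 1:6] == 0) > 0.99)
  # nocturia's first threshold (-7.89) leaves a visible nonzero fraction
  p_nz <- 1 - category_probabilities(tru$bank$items[[7L]], -10)[1L, 1L]
  expect_gt(p_nz, 0.2)
})

test_that("empirical category frequencies match the model probabilities", {
  it <- uni_bank()$items[[4L]]
  psi0 <- -0.5
  n <- 1e5
  set.seed(31)
  p <- category_probabilities(it, psi0)[1L, ]
  draws <- sample(0:5, n, replace = TRUE, prob = p)  # inverse-cdf reference
  # package simulation path at a fixed latent value
  tru <- zero_iiv_truth("unidimensional")
  traj <- data.frame(patient_id = 1L, time_months = seq_len(n) / n,
                     visit_idx = seq_len(n), psi1 = psi0)
  des <- trial_design(n_patients = 1L, screening_threshold = -Inf, seed = 2L)
  pop <- generate_population(des, tru)
  dat <- generate_item_responses(traj, tru$bank, des, pop)
  f <- tabulate(dat$item4 + 1L, 6L) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(f - p) <= 3 * se + 1e-12))
  # and the reference sampler agrees too
  f2 <- tabulate(draws + 1L, 6L) / n
  expect_true(all(abs(f2 - p) <= 3 * se + 1e-12))
})

test_that("baseline latent disability is standard normal under IDVIS
          simulation", {
  d <- simulate_idvis_dataset(uni_bank(), uni_shift(), n_patients = 2500L,
                              visit_times = c(0, 1, 2, 3), seed = 15L)
  psi <- attr(d, "psi")[d$time_months == 0, 1L]
  expect_gt(ks.test(psi, pnorm)$p.value, 0.01)
})

test_that("missingness and dropout thin the records as configured", {
  des <- trial_design(n_patients = 60L, item_missingness_rate = 0.1,
                      dropout_rate = 0.15, screening_threshold = -Inf,
                      seed = 44L)
  dat <- simulate_trial(des, simulation_truth())
  it <- as.matrix(dat[paste0("item", 1:7)])
  miss <- mean(is.na(it))
  expect_gt(miss, 0.05); expect_lt(miss, 0.15)
  expect_lt(nrow(dat), 60L * 8L)          # dropout removed visits
  expect_true(all(is.na(dat$total[rowSums(is.na(it)) > 0L])))
  # dropout is monotone: no gaps within a patient's retained visits
  for (id in unique(dat$patient_id)) {
    v <- sort(dat$visit_idx[dat$patient_id == id])
    expect_equal(v, seq_along(v))
  }
})
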