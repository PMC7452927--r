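# IDVIS reshaping, marginal-likelihood machinery, ICC fitting, EBEs and
# shrinkage.

test_that("IDVIS reshape creates one pseudo-individual per patient-visit
          and round-trips", {
  d <- small_bi_data()
  ps <- reshape_idvis(d)
  expect_equal(nrow(ps), nrow(d))
  expect_equal(sum(ps$origin == "baseline"), 120L)
  back <- reassemble_idvis(ps)
  expect_equal(back$patient_id, d$patient_id)
  expect_equal(back$item3, d$item3)
  expect_equal(back$total, d$total)
  # a missed visit just drops that pseudo-individual
  d2 <- d[-5L, ]
  ps2 <- reshape_idvis(d2)
  expect_equal(nrow(ps2), nrow(d) - 1L)
  # duplicates are rejected
  expect_error(reshape_idvis(rbind(d, d[1L, ])), "duplicate")
})

test_that("adaptive 21-node quadrature agrees with 101-node fixed
          quadrature on a 50-pseudo-individual fixture", {
  d <- simulate_idvis_dataset(uni_bank(), uni_shift(), n_patients = 25L,
                              visit_times = c(0, 3), seed = 123L)
  o_agh <- icc_ofv(uni_bank(), uni_shift(), d, method = "agh", nodes = 21L)
  o_ghq <- icc_ofv(uni_bank(), uni_shift(), d, method = "ghq", nodes = 101L)
  expect_lt(abs(o_agh[1L] - o_ghq[1L]), 0.01)
})

test_that("duplicating every row doubles the OFV and leaves estimates
          unchanged", {
  d <- simulate_idvis_dataset(uni_bank(), uni_shift(), n_patients = 80L,
                              visit_times = c(0, 3), seed = 9L)
  f1 <- fit_icc(d, 1L, se = FALSE, max_iter = 200L)
  d2 <- d
  d2$patient_id <- d2$patient_id + 1000L
  dd <- rbind(d, d2)
  f2 <- fit_icc(dd, 1L, se = FALSE, max_iter = 200L)
  a1 <- vapply(f1$bank$items, `[[`, numeric(1L), "a")
  a2 <- vapply(f2$bank$items, `[[`, numeric(1L), "a")
  expect_equal(a2, a1, tolerance = 0.02)
  expect_equal(f2$ofv, 2 * f1$ofv, tolerance = 0.001)
})

test_that("baseline-only data leaves the shift non-identified", {
  d <- simulate_idvis_dataset(uni_bank(), uni_shift(), n_patients = 60L,
                              visit_times = 0, seed = 2L)
  expect_warning(f <- fit_icc(d, 1L, se = FALSE, max_iter = 40L),
                 "not identified")
  expect_false(f$shift_identified)
  expect_true(all(is.na(f$shift$post_mean)))
  expect_equal(f$n_params, 42L)
})

test_that("bidimensional fit lowers the OFV relative to unidimensional on
          two-dimensional data", {
  d <- small_bi_data()
  f1 <- fit_icc(d, 1L, se = FALSE, max_iter = 150L)
  f2 <- small_bi_fit()
  expect_equal(f1$n_params, 44L)
  expect_equal(f2$n_params, 47L)
  expect_lt(f2$ofv, f1$ofv)
  expect_true(abs(f2$shift$correlation) < 1)
})

test_that("MAP disability estimates match a fine grid search and behave at
          the extremes", {
  f <- list(bank = uni_bank(), shift = uni_shift(), n_dimensions = 1L)
  class(f) <- "icc_fit"
  set.seed(5)
  for (r in 1:12) {
    pat <- sample(0:5, 7, replace = TRUE)
    origin <- sample(c("baseline", "post"), 1L)
    e <- estimate_ebe(f$bank, f$shift, pat, origin)
    grid <- seq(-10, 10, by = 0.001)
    pm <- if (origin == "baseline") 0 else f$shift$post_mean
    psd <- if (origin == "baseline") 1 else sqrt(f$shift$post_variance)
    lp <- vapply(grid, function(p) response_loglik(f$bank, p, pat),
                 numeric(1L)) + dnorm(grid, pm, psd, log = TRUE)
    expect_lt(abs(e$ebe - grid[which.max(lp)]), 0.01)
    expect_gt(e$se, 0)
  }
  # no observed items: the prior is returned
  e0 <- estimate_ebe(f$bank, f$shift, rep(NA, 7), "post")
  expect_equal(e0$ebe, f$shift$post_mean)
  expect_equal(e0$se, sqrt(f$shift$post_variance))
  # an all-zero pattern at baseline sits below the prior mean
  ez <- estimate_ebe(f$bank, f$shift, rep(0L, 7), "baseline")
  expect_lt(ez$ebe, 0)
})

test_that("shrinkage is near zero for perfect estimates and complete for
          uninformative items", {
  f <- list(bank = uni_bank(), shift = uni_shift(), n_dimensions = 1L)
  class(f) <- "icc_fit"
  # EBEs equal to true draws: typical SD-shrinkage ~ 0
  set.seed(21)
  n <- 2000L
  truth_draws <- rnorm(n, f$shift$post_mean, sqrt(f$shift$post_variance))
  est <- data.frame(patient_id = seq_len(n), time_months = 3, origin = "post",
                    dim = 1L, ebe = truth_draws, se = 0.3)
  class(est) <- c("ebe_table", "data.frame")
  s <- shrinkage(f, est)
  expect_lt(abs(s[[1L]]$typical), 0.06)
  # near-zero discrimination: EBEs collapse to the prior mean
  flat <- item_bank(lapply(1:7, function(j)
    item_parameters(j, 1e-4, uni_bank()$items[[j]]$thresholds)), 1L)
  d <- simulate_idvis_dataset(flat, uni_shift(), n_patients = 60L,
                              visit_times = c(0, 3), seed = 3L)
  ff <- list(bank = flat, shift = uni_shift(), n_dimensions = 1L)
  class(ff) <- "icc_fit"
  eb <- disability_estimates(ff, d)
  s2 <- shrinkage(ff, eb)
  expect_gt(s2[[1L]]$typical, 0.95)
  expect_error(shrinkage(f, est[1L, ]), "two estimates")
})

test_that("bidimensional disability estimates respect the item-dimension
          assignment", {
  f <- list(bank = bi_bank(), shift = bi_shift(), n_dimensions = 2L)
  class(f) <- "icc_fit"
  d <- small_bi_data()
  eb <- disability_estimates(f, d)
  expect_equal(nrow(eb), 2L * nrow(d))
  expect_true(all(eb$se > 0))
  # high voiding scores with zero storage scores should split the estimates
  pat <- c(5L, 0L, 5L, 0L, 5L, 5L, 0L)
  e <- estimate_ebe(f$bank, f$shift, pat, "post")
  expect_gt(e$ebe[1L], e$ebe[2L])
})
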