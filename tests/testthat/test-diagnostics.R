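# Sampling-based GAM ICC check, residual item correlations, and VPCs.

test_that("the GAM check accepts a well-specified model and flags a halved
          discrimination", {
  fx <- diag_fixture()
  chk <- sampled_gam_icc_check(fx$fit, fx$ebe, fx$data, n_samples = 20L,
                               seed = 4L)
  expect_equal(nrow(chk$panels), 35L)
  expect_lte(mean(chk$panels$flagged), 0.10)
  # misspecification: data simulated with item 1 discrimination halved
  bad_bank <- uni_bank()
  bad_bank$items[[1L]] <- item_parameters(1L, uni_bank()$items[[1L]]$a / 2,
                                          uni_bank()$items[[1L]]$thresholds)
  d_bad <- simulate_idvis_dataset(bad_bank, uni_shift(), n_patients = 150L,
                                  visit_times = c(0, 1, 3, 6), seed = 20L)
  eb_bad <- disability_estimates(fx$fit, d_bad)
  chk_bad <- sampled_gam_icc_check(fx$fit, eb_bad, d_bad, n_samples = 20L,
                                   seed = 4L)
  flagged1 <- chk_bad$panels$flagged[chk_bad$panels$item == 1L]
  expect_gte(sum(flagged1), 1L)
  expect_gt(sum(chk_bad$panels$flagged), sum(chk$panels$flagged))
})

test_that("the band multiplier and the degenerate single-sample limit
          behave as documented", {
  fx <- diag_fixture()
  expect_equal(sqrt(200), 14.14, tolerance = 0.001)
  e0 <- fx$ebe
  e0$se <- rep(0, nrow(e0))
  chk1 <- sampled_gam_icc_check(fx$fit, e0, fx$data, n_samples = 1L,
                                seed = 5L)
  # with one sample at zero SE every draw equals the EBE itself
  expect_equal(nrow(chk1$curves), 35L * 100L)
  expect_error(sampled_gam_icc_check(fx$fit, fx$ebe, fx$data,
                                     n_samples = 0L), "n_samples")
})

test_that("residual correlations are symmetric, small under local
          independence, and detect an injected shared shock", {
  fx <- diag_fixture()
  cm <- residual_correlation(fx$fit, fx$ebe, fx$data)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 7))
  off <- abs(cm[upper.tri(cm)])
  expect_gte(mean(off < 0.25), 0.95)
  # inject a shared latent shock into items 2 and 4
  set.seed(9)
  d <- fx$data
  shock <- rnorm(nrow(d), 0, 1.5)
  psi <- attr(d, "psi")[, 1L]
  for (j in c(2L, 4L)) {
    p <- category_probabilities(uni_bank()$items[[j]], psi + shock)
    cp <- t(apply(p, 1L, cumsum))
    u <- runif(nrow(d))
    d[[paste0("item", j)]] <- as.integer(pmin(rowSums(u > cp), 5L))
  }
  eb <- disability_estimates(fx$fit, d)
  cm2 <- residual_correlation(fx$fit, eb, d)
  expect_gt(cm2["item2", "item4"], 0.25)
  # identical response patterns give residuals with no variance at all
  d0 <- fx$data[rep(1L, 40L), ]
  d0$patient_id <- seq_len(40L)
  eb0 <- disability_estimates(fx$fit, d0)
  expect_error(residual_correlation(fx$fit, eb0, d0), "zero residual")
})

test_that("VPC covers the observed medians under the true model and flags
          a shifted dataset", {
  vf <- vpc_fixture()
  dat <- vf$data; fit <- vf$fit
  v <- vpc(fit, dat, n_sim = 200L, seed = 6L)
  expect_gte(v$coverage, 0.9)
  shifted <- dat
  shifted$total <- shifted$total + 5
  v2 <- vpc(fit, shifted, n_sim = 200L, seed = 6L)
  expect_lt(v2$coverage, 0.5)
  expect_error(vpc(fit, dat, n_sim = 10L), "at least 20")
})

test_that("item-level VPC works from a simulation truth and its intervals
          tighten with more simulations", {
  tru <- simulation_truth()
  des <- trial_design(n_patients = 60L, visit_times = c(0, 1, 3, 6),
                      seed = 3L)
  dat <- simulate_trial(des, tru)
  v <- vpc(tru, dat, n_sim = 40L, level = "item", seed = 8L)
  expect_equal(sort(unique(v$table$item)), 1:7)
  expect_gte(v$coverage, 0.8)
  # the simulated band is a prediction interval across replicates: its
  # width stabilizes (converges) as n_sim grows rather than shrinking
  v_small <- vpc(tru, dat, n_sim = 60L, seed = 9L)
  v_big <- vpc(tru, dat, n_sim = 240L, seed = 9L)
  w_small <- mean(v_small$table$hi - v_small$table$lo)
  w_big <- mean(v_big$table$hi - v_big$table$lo)
  expect_lt(abs(w_big - w_small) / w_small, 0.25)
  # change-from-baseline VPC stratifies by arm
  v3 <- vpc(tru, dat, n_sim = 30L, change_from_baseline = TRUE, seed = 10L)
  expect_setequal(unique(v3$table$arm), c("placebo", "active"))
})
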