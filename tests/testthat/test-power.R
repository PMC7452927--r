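# ANCOVA estimands, threshold calibration, and the SSE machinery at toy
# scale. Full-fidelity power curves are a production run
# (see the methods vignette); the acceptance suite checks a scaled-down
# configuration.

# deterministic little trial frame builder
toy_trial <- function(n, times, effect = 0, noise = 1, seed = 1) {
  set.seed(seed)
  base <- rnorm(n, 19, 3)
  active <- rep(c(FALSE, TRUE), length.out = n)
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(patient_id = i, arm = if (active[i]) "20mg" else "placebo",
               dose_mg = if (active[i]) 20 else 0, time_months = times,
               total = base[i] + ifelse(times > 0, effect * active[i], 0) +
                 rnorm(length(times), 0, noise))))
}

test_that("cross-sectional ANCOVA matches a hand-rolled least-squares
          oracle on a six-patient fixture", {
  d <- data.frame(
    patient_id = 1:6,
    arm = c("placebo", "placebo", "placebo", "10mg", "10mg", "10mg"),
    dose_mg = c(0, 0, 0, 10, 10, 10))
  d0 <- transform(d, time_months = 0, total = c(18, 21, 15, 20, 17, 23))
  d3 <- transform(d, time_months = 3, total = c(16, 20, 15, 14, 12, 19))
  dat <- rbind(d0, d3)
  p <- ancova_cross_sectional(dat)
  # explicit normal equations + t distribution
  y <- d3$total - d0$total
  X <- cbind(1, as.numeric(d$dose_mg > 0), d0$total)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (6 - 3)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  p_oracle <- 2 * pt(abs(beta[2] / se), df = 3, lower.tail = FALSE)
  expect_equal(p, p_oracle, tolerance = 1e-10)
})

test_that("ANCOVA p-values are uniform under the null and tiny under a
          deterministic shift", {
  ps <- vapply(1:300, function(r)
    ancova_cross_sectional(toy_trial(40L, c(0, 3), effect = 0, seed = r)),
    numeric(1L))
  expect_gt(ks.test(ps, punif)$p.value, 0.01)
  d <- toy_trial(30L, c(0, 3), effect = -5, noise = 0.01, seed = 4)
  expect_lt(ancova_cross_sectional(d), 1e-6)
})

test_that("the while-on-treatment estimand reduces to the cross-sectional
          test with a single post-baseline visit and gains power with
          more", {
  d <- toy_trial(40L, c(0, 3), effect = -2, seed = 11)
  expect_equal(ancova_wot(d), ancova_cross_sectional(d), tolerance = 1e-12)
  ps <- vapply(1:300, function(r)
    ancova_wot(toy_trial(40L, c(0, 1, 2, 3, 4, 5, 6), effect = 0,
                         seed = 1000 + r)), numeric(1L))
  expect_gt(ks.test(ps, punif)$p.value, 0.01)
  # averaging over visits reduces residual noise: WOT >= cross-sectional
  hits <- function(fn) mean(vapply(1:120, function(r)
    fn(toy_trial(24L, c(0, 1, 2, 3, 4, 5, 6), effect = -1.5, noise = 3,
                 seed = 5000 + r)) < 0.05, numeric(1L)))
  expect_gte(hits(ancova_wot), hits(ancova_cross_sectional))
})

test_that("the four-level-factor ANCOVA variant runs and agrees
          directionally", {
  d <- toy_trial(60L, c(0, 3), effect = -3, seed = 21)
  expect_lt(ancova_cross_sectional(d, factor = "arm"), 0.05)
})

test_that("empirical threshold calibration matches the chi-squared cutoff
          for a correctly specified linear-Gaussian toy model", {
  set.seed(77)
  n <- 100L
  dofv <- vapply(1:1000, function(r) {
    y <- rnorm(n)
    x <- rep(c(0, 1), each = n / 2)
    rss1 <- sum(lm.fit(cbind(1, x), y)$residuals^2)
    rss0 <- sum((y - mean(y))^2)
    n * log(rss0 / rss1)
  }, numeric(1L))
  thr <- calibrate_dofv(dofv)
  expect_equal(thr, qchisq(0.95, 1L), tolerance = 0.2)
  # applying the threshold back to the null replicates rejects ~5%
  expect_equal(mean(dofv > thr), 0.05, tolerance = 0.005)
  expect_warning(calibrate_dofv(dofv[1:50]), "unstable")
})

test_that("80%-power interpolation is monotone and exact on crossing
          grids", {
  expect_equal(interpolate_n80(c(33, 66, 99, 137), c(0.4, 0.7, 0.85, 0.95)),
               66 + (0.8 - 0.7) / 0.15 * 33, tolerance = 1e-9)
  expect_true(is.na(interpolate_n80(c(33, 66), c(0.9, 0.95))))
  # non-monotone inputs are pooled before interpolation
  expect_false(is.na(interpolate_n80(c(33, 66, 99), c(0.5, 0.9, 0.85))))
})

test_that("a tenfold drug effect saturates ANCOVA power and the null truth
          keeps its size", {
  tru <- simulation_truth(bank = reference_item_bank("bidimensional"),
                          longitudinal = reference_longitudinal("bidimensional"))
  big <- tru
  big$longitudinal$theta[grep("^drug", names(big$longitudinal$theta))] <-
    10 * big$longitudinal$theta[grep("^drug", names(big$longitudinal$theta))]
  pw_big <- sse_power(big, n_grid = 30L, n_reps = 15L, n_null_reps = 0L,
                      methods = c("ancova3m", "ancovawot"), seed = 2L)
  expect_true(all(pw_big$power == 1))
  pw_null <- sse_power(ipssirt:::null_truth(tru), n_grid = 40L,
                       n_reps = 80L, n_null_reps = 0L,
                       methods = "ancova3m", seed = 3L)
  expect_lt(pw_null$power, 0.13)
})

test_that("Wilson intervals contain the point estimate", {
  ci <- ipssirt:::wilson_ci(8, 10)
  expect_true(ci[1] < 0.8 && ci[2] > 0.8)
  expect_true(all(ci >= 0 & ci <= 1))
})
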