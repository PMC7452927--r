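# Graded-response model mathematics.

test_that("reported difficulty values convert to ordered thresholds", {
  expect_equal(thresholds_from_increments(c(-4.09, 1.82, 1.68, 1.41, 1.27)),
               c(-4.09, -2.27, -0.59, 0.82, 2.09))
  expect_equal(thresholds_from_increments(-2), -2)
  expect_error(thresholds_from_increments(c(0, -1, 1, 1, 1)), "positive")
})

test_that("cumulative probabilities follow the two-parameter logistic", {
  it1 <- uni_bank()$items[[1L]]
  expect_equal(cumulative_probability(it1, it1$thresholds[2L], 2), 0.5)
  expect_equal(cumulative_probability(it1, 1e4, 1), 1)
  # item 1, a = 1.38, tau1 = -4.09, psi = 0
  expect_equal(cumulative_probability(it1, 0, 1),
               1 / (1 + exp(-1.38 * 4.09)), tolerance = 1e-12)
  expect_error(cumulative_probability(it1, 0, 6), "category")
  # non-increasing in k, non-decreasing in psi
  ks <- vapply(1:5, function(k) cumulative_probability(it1, 0.3, k),
               numeric(1L))
  expect_true(all(diff(ks) <= 0))
  expect_true(all(diff(cumulative_probability(it1, seq(-6, 6, 0.5), 3)) > 0))
})

test_that("category probabilities are a proper distribution and match a
          brute-force evaluation", {
  bank <- uni_bank()
  for (j in c(1L, 4L, 7L)) {
    p <- category_probabilities(bank$items[[j]], c(-3, 0, 2.5))
    expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  expect_equal(category_probabilities(bank$items[[2L]], -1e4)[1L, ],
               c("0" = 1, "1" = 0, "2" = 0, "3" = 0, "4" = 0, "5" = 0))
  # independent brute force from the two defining equations
  it <- bank$items[[1L]]
  cum <- c(1, plogis(it$a * (0 - it$thresholds)), 0)
  expect_equal(unname(category_probabilities(it, 0)[1L, ]),
               cum[1:6] - cum[2:7], tolerance = 1e-12)
})

test_that("expected score is the category-probability mean and increases
          with disability", {
  it <- uni_bank()$items[[3L]]
  p <- category_probabilities(it, 0.7)
  expect_equal(expected_score(it, 0.7), sum(p * (0:5)), tolerance = 1e-12)
  expect_true(all(diff(expected_score(it, seq(-8, 8, 0.25))) > 0))
  # degenerate distribution at the top category
  hi <- item_parameters(1, 20, c(-30, -29, -28, -27, -26))
  expect_equal(expected_score(hi, 0), 5, tolerance = 1e-6)
  # nocturia at low disability: most patients still score at least 1
  e7 <- expected_score(uni_bank()$items[[7L]], -4)
  expect_gt(e7, 0.87)
})

test_that("item information matches the dichotomous closed form and the
          expected negative second derivative", {
  # single-threshold item at its threshold: a^2 P (1 - P) = a^2 / 4
  it <- item_parameters(1, 2, 0)
  expect_equal(item_information(it, 0), 1, tolerance = 1e-10)
  # nonnegative over a wide grid for all reference items
  grid <- seq(-8, 8, length.out = 101L)
  for (item in uni_bank()$items)
    expect_true(all(item_information(item, grid) >= 0))
  # Monte-Carlo: - mean d2/dpsi2 log P_y over simulated scores at fixed psi
  set.seed(42)
  it1 <- uni_bank()$items[[1L]]
  psi0 <- 0.4
  draws <- local({  # simulate via the category distribution directly
    p <- category_probabilities(it1, psi0)[1L, ]
    sample(0:5, 1e6, replace = TRUE, prob = p)
  })
  h <- 1e-4
  lp <- function(psi) log(category_probabilities(it1, psi)[1L, ])
  d2 <- (lp(psi0 + h) - 2 * lp(psi0) + lp(psi0 - h)) / h^2
  mc_info <- -mean(d2[draws + 1L])
  expect_equal(mc_info, item_information(it1, psi0), tolerance = 0.02)
})

test_that("response log-likelihood sums observed items and handles
          missingness", {
  bank <- uni_bank()
  expect_equal(response_loglik(bank, 0.3, rep(NA, 7)), 0)
  expect_equal(response_loglik(bank, -1, c(2, rep(NA, 6))),
               unname(log(category_probabilities(bank$items[[1L]],
                                                 -1)[1L, 3L])))
  set.seed(7)
  pat <- sample(0:5, 7, replace = TRUE)
  brute <- sum(vapply(1:7, function(j)
    log(category_probabilities(bank$items[[j]], 0.9)[1L, pat[j] + 1L]),
    numeric(1L)))
  expect_equal(response_loglik(bank, 0.9, pat), brute, tolerance = 1e-12)
  expect_error(response_loglik(bank, 0, c(6, rep(0, 6))), "outside")
})

test_that("a bidimensional bank at equal, perfectly aligned coordinates
          reproduces the unidimensional likelihood", {
  b2 <- bi_bank()
  items1 <- lapply(b2$items, function(it)
    item_parameters(it$item, it$a, it$thresholds, "general"))
  b1 <- item_bank(items1, 1L)
  set.seed(11)
  for (r in 1:5) {
    pat <- sample(0:5, 7, replace = TRUE)
    psi <- rnorm(1)
    expect_equal(response_loglik(b2, c(psi, psi), pat),
                 response_loglik(b1, psi, pat), tolerance = 1e-12)
  }
})

test_that("item parameter validation rejects invalid inputs", {
  expect_error(item_parameters(1, -1, c(-1, 0)), "positive")
  expect_error(item_parameters(1, 1, c(0, -1)), "increasing")
  its <- lapply(1:7, function(j) item_parameters(j, 1, 0))
  expect_error(item_bank(c(its[1:6], its[1L]), 1L), "unique")
  expect_error(item_bank(its, 2L), "voiding")
})
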