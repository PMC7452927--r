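# Fisher-information curves and ranking.

test_that("identical items share the information equally and curves match
          the per-item information", {
  items <- lapply(1:7, function(j)
    item_parameters(j, 1.1, c(-3, -1.5, 0, 1.5, 3)))
  b <- item_bank(items, 1L)
  rep_ <- information_share(b, c(-4, 4))
  expect_equal(rep_$share, rep(100 / 7, 7), tolerance = 1e-9)
  cv <- information_curves(b, seq(-3, 3, length.out = 21L))
  one <- cv[cv$item == 1L, ]
  expect_equal(one$information,
               item_information(b$items[[1L]], one$psi))
  for (j in 2:7)
    expect_equal(cv$information[cv$item == j], one$information)
})

test_that("bidimensional banks are rejected for information ranking", {
  expect_error(information_curves(bi_bank()), "unidimensional")
  expect_error(information_share(bi_bank(), c(-4, 4)), "unidimensional")
})

test_that("a higher-discrimination item dominates near common thresholds", {
  th <- c(-2, -1, 0, 1, 2)
  hi <- item_parameters(1, 2, th)
  lo <- item_parameters(2, 0.8, th)
  grid <- seq(-2.5, 2.5, length.out = 41L)
  expect_true(all(item_information(hi, grid) > item_information(lo, grid)))
})

test_that("shares are stable under grid refinement", {
  b <- uni_bank()
  s1 <- information_share(b, c(-4, 4), grid_points = 2001L)
  s2 <- information_share(b, c(-4, 4), grid_points = 8001L)
  expect_true(all(abs(s1$share - s2$share[match(s1$item, s2$item)]) < 0.05))
})

test_that("over an effectively infinite range, single-threshold items carry
          shares proportional to their discriminations", {
  a <- c(0.5, 0.8, 1.1, 1.4, 1.7, 2.0, 2.3)
  items <- lapply(1:7, function(j) item_parameters(j, a[j], 0))
  b <- item_bank(items, 1L)
  rep_ <- information_share(b, c(-60, 60), grid_points = 6001L)
  expected <- 100 * a / sum(a)
  expect_equal(rep_$share[order(rep_$item)], expected, tolerance = 0.01)
})

test_that("the reference bank ranks incomplete emptying first and nocturia
          last across the sensitivity sweep, with voiding items near 72%", {
  b <- uni_bank()
  sweep <- information_sensitivity(b)
  for (rep_ in sweep) {
    expect_equal(rep_$label[1L], "incomplete emptying")
    expect_equal(rep_$label[7L], "nocturia")
    v <- sum(rep_$share[rep_$subscore == "voiding"])
    expect_gt(v, 68); expect_lt(v, 76)
  }
})
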