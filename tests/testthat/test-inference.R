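test_that("continuous AD statistic reproduces the direct double-sum", {
  r <- ad_2sample(c(1, 2, 3), c(4, 5, 6), version = "continuous")
  expect_equal(r$statistic, 2.4, tolerance = 1e-12)
  expect_equal(r$statistic, brute_force_ad_continuous(1:3, 4:6),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1))
    y <- rnorm(sample(3:10, 1))
    expect_equal(ad_2sample(x, y, version = "continuous")$statistic,
                 brute_force_ad_continuous(x, y), tolerance = 1e-10)
  }
})

test_that("ties-adjusted standardized statistic matches the reference values", {
  # frozen from an independent midrank implementation
  # (scipy.stats.anderson_ksamp)
  expect_equal(ad_2sample(c(1, 2, 3), c(4, 5, 6))$standardized,
               2.6332335269661775, tolerance = 1e-9)
  expect_equal(ad_2sample(c(1, 3, 5, 7, 9, 11),
                          c(2, 4, 6, 8, 10, 12))$standardized,
               -1.1101552661170608, tolerance = 1e-9)
  expect_equal(ad_2sample(c(1, 1, 2, 3, 5, 5, 7),
                          c(1, 2, 2, 4, 5, 6, 8, 8))$standardized,
               -0.5361116581392313, tolerance = 1e-9)
  x <- c(0.001, 0.299, -0.274, -0.891, -0.455, -0.992, 0.06, 1.34,
         -0.492, -0.62, 0.49, 0.357)
  y <- c(-0.738, -0.337, -0.361, 0.648, -1.313, 0.811, 0.043, 1.894,
         1.957, 2.392, 1.767, 0.947, 1.86, 2.505, 0.346)
  r <- ad_2sample(x, y)
  expect_equal(r$standardized, 2.405202816752645, tolerance = 1e-9)
  # interpolated p near the independent implementation's value
  expect_equal(r$p_value, 0.0335, tolerance = 0.01)
})

test_that("AD p-value interpolation hits the asymptotic anchor points", {
  # the published m = 1 percentile pairs must be reproduced exactly
  anchors <- data.frame(t = c(0.326, 1.225, 1.960, 2.719, 3.752),
                        p = c(0.25, 0.10, 0.05, 0.025, 0.01))
  for (i in seq_len(nrow(anchors))) {
    expect_equal(cibr:::ad_pvalue_asymptotic(anchors$t[i]), anchors$p[i],
                 tolerance = 1e-9)
  }
  # monotone decreasing in t, also beyond the table
  ts <- seq(-2, 8, by = 0.25)
  ps <- vapply(ts, cibr:::ad_pvalue_asymptotic, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps < 1))
})

test_that("AD test validates input and behaves symmetrically", {
  expect_error(ad_2sample(1, c(1, 2)), "at least 2")
  x <- rnorm(8)
  y <- rnorm(9)
  expect_equal(ad_2sample(x, y)$statistic, ad_2sample(y, x)$statistic,
               tolerance = 1e-12)
  # rank invariance: strictly increasing transforms leave the test unchanged
  r1 <- ad_2sample(x, y)
  r2 <- ad_2sample(exp(x), exp(y))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("AD permutation p is 1 for mirrored samples and never 0", {
  x <- c(1, 2, 2, 3, 7)
  r <- ad_2sample(x, x, method = "permutation", n_permutations = 200,
                  seed = 3)
  expect_equal(r$p_value, 1)
  far <- ad_2sample(1:6, 101:106, method = "permutation",
                    n_permutations = 500, seed = 3)
  expect_gte(far$p_value, 1 / 501)
})

test_that("dominance statistic and exhaustive p match explicit enumeration", {
  r <- dominance_test(c(1, 2, 3), c(101, 102, 103), "x_below_y")
  expect_equal(r$statistic, 1)
  expect_equal(r$p_value, 1 / 20)
  expect_true(r$exhaustive)

  same <- dominance_test(c(5, 5, 5), c(5, 5, 5), "x_below_y")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  set.seed(40)
  for (i in 1:10) {
    x <- round(rnorm(sample(3:5, 1)), 1)
    y <- round(rnorm(sample(3:5, 1), mean = 0.5), 1)
    mine <- dominance_test(x, y, "x_below_y")
    oracle <- brute_force_dominance_p(x, y)
    expect_equal(mine$statistic, oracle$d, tolerance = 1e-12)
    expect_equal(mine$p_value, oracle$p, tolerance = 1e-12)
  }
  expect_error(dominance_test(1:3, 4:6, "sideways"), "unknown direction")
  expect_error(dominance_test(1:20, 21:40, n_permutations = 0),
               "n_permutations")
})

test_that("Monte-Carlo dominance p agrees with the exhaustive p", {
  set.seed(8)
  x <- rnorm(5)
  y <- rnorm(5, mean = 1)
  exact <- dominance_test(x, y, "x_below_y")$p_value
  B <- 1e5
  mc <- dominance_test(x, y, "x_below_y", n_permutations = B, seed = 11,
                       exhaustive_threshold = 0L)
  se <- sqrt(exact * (1 - exact) / B)
  expect_false(mc$exhaustive)
  expect_lt(abs(mc$p_value - exact), 3 * se + 1 / B)
})

test_that("dominance direction mirrors under negation", {
  set.seed(12)
  x <- rnorm(9)
  y <- rnorm(7, 0.4)
  d_xy <- dominance_test(x, y, "x_below_y", n_permutations = 10)$statistic
  d_neg <- dominance_test(-x, -y, "y_below_x", n_permutations = 10)$statistic
  expect_equal(d_xy, d_neg, tolerance = 1e-12)
})

test_that("compare_groups gates dominance on the AD stage and labels verdicts", {
  set.seed(21)
  x <- list(P = rnorm(40, 0.2, 0.05), O = rnorm(40, 0.2, 0.05))
  y <- list(P = rnorm(40, 0.5, 0.05), O = rnorm(40, 0.2, 0.05),
            Z = rnorm(40))
  res <- compare_groups(x, y, alpha = 0.01, n_permutations = 500, seed = 5,
                        group_x = "cons", group_y = "ref")
  expect_setequal(res$category, c("P", "O"))  # Z not shared
  p_row <- res[res$category == "P", ]
  expect_equal(p_row$verdict, "x_stochastically_smaller")
  expect_lte(p_row$ad_p, 0.01)
  o_row <- res[res$category == "O", ]
  expect_equal(o_row$verdict, "same")
  expect_true(is.na(o_row$dom_xy_p))  # dominance stage never ran

  # undefined CIB values are dropped with counts reported
  x2 <- list(P = c(rnorm(30, 0.2, 0.05), NA, NA))
  y2 <- list(P = rnorm(30, 0.5, 0.05))
  res2 <- compare_groups(x2, y2, n_permutations = 200, seed = 5)
  expect_equal(res2$n_dropped_x, 2L)
  expect_equal(res2$n_x, 30L)

  # a category too small in one group is skipped with a logged reason
  x3 <- list(P = rnorm(20), Q = 0.3)
  y3 <- list(P = rnorm(20), Q = rnorm(20))
  expect_message(res3 <- compare_groups(x3, y3, n_permutations = 50,
                                        seed = 2), "skipped")
  expect_equal(res3$category, "P")
  expect_match(attr(res3, "skipped"), "^Q")

  expect_error(compare_groups(list(A = 1:5), list(B = 1:5)),
               "no category")
})

test_that("identically distributed groups are mostly called 'same'", {
  set.seed(77)
  cats <- paste0("C", 1:60)
  x <- stats::setNames(lapply(cats, function(i) runif(30)), cats)
  y <- stats::setNames(lapply(cats, function(i) runif(30)), cats)
  res <- compare_groups(x, y, alpha = 0.05, n_permutations = 100, seed = 4)
  # AD stage false-positive rate should be near alpha
  expect_lt(mean(res$verdict != "same"), 0.2)
})
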