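test_that("coefficient of variation matches its definition and edge cases", {
  expect_equal(cv_from_moments(0.512, 0.150), 29.3, tolerance = 0.01)
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(cv_from_moments(0, 1), "zero mean")
  # scale invariance for positive scalars
  set.seed(1)
  x <- runif(20, 1, 5)
  expect_equal(coefficient_of_variation(3 * x), coefficient_of_variation(x),
               tolerance = 1e-12)
})

test_that("Cohen's d is the mean gap over the average-pooled sd", {
  expect_equal(cohens_d(3, 1, 3, 2), 0)
  expect_equal(cohens_d(1, 1, 0, 1), 1)
  expect_equal(cohens_d(0.442, 0.078, 0.512, 0.150), 0.5855, tolerance = 1e-3)
  expect_equal(cohens_d(1, 0.5, 2, 1.5), cohens_d(2, 1.5, 1, 0.5))
  expect_error(cohens_d(1, 0, 2, 0), "both standard deviations zero")
})

test_that("the paired t-test matches stats::t.test and is degenerate-safe", {
  set.seed(2)
  a <- rnorm(10); b <- a + rnorm(10, 0.5)
  r <- paired_t(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)

  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_false(same$significant)
  expect_error(paired_t(a, a + 1), "zero-variance")
})

test_that("paired t-test holds its nominal type-I error", {
  set.seed(11)
  rejections <- 0
  for (k in 1:1000) {
    a <- rnorm(20); b <- rnorm(20)
    if (paired_t(a, b)$significant) rejections <- rejections + 1
  }
  expect_gte(rejections / 1000, 0.03)
  expect_lte(rejections / 1000, 0.07)
})

test_that("Kruskal-Wallis matches the hand-ranked H and is rank-invariant", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-9)
  expect_equal(r$H, 3.857, tolerance = 1e-3)

  same <- kruskal_wallis(list(c(2, 2, 2), c(2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  # invariance under strictly monotone transforms of the pooled values
  set.seed(4)
  g1 <- runif(8, 0, 2); g2 <- runif(8, 0.5, 2.5); g3 <- runif(8, 1, 3)
  h0 <- kruskal_wallis(list(g1, g2, g3))$H
  h1 <- kruskal_wallis(list(exp(g1), exp(g2), exp(g3)))$H
  expect_equal(h0, h1, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
})

test_that("regression and clustering reproduce simple geometry", {
  x <- c(1, 2, 3, 4)
  r <- regression_slope(x, x)
  expect_equal(r$slope, 1)
  expect_equal(r$r, 1)
  r2 <- regression_slope(x, 2 * x + 1)
  expect_equal(r2$slope, 2)
  expect_equal(r2$intercept, 1)
  expect_error(regression_slope(c(1, 1, 1), 1:3), "zero variance")

  pts <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  hc <- hierarchical_cluster(pts, standardize = FALSE)
  expect_equal(hc$height[1], 0)
  # three collinear points: nearest pair merges first
  pts2 <- rbind(p0 = c(0, 0), p1 = c(1, 0), p10 = c(10, 0))
  hc2 <- hierarchical_cluster(pts2, standardize = FALSE)
  first <- sort(abs(hc2$merge[1, ]))
  expect_equal(hc2$labels[first], c("p0", "p1"))
  expect_error(hierarchical_cluster(rbind(a = c(1, 1), a = c(2, 2))),
               "duplicate")
})

test_that("ANOVA with Tukey flags only genuinely shifted groups", {
  set.seed(2)
  base <- list(g1 = rnorm(10), g2 = rnorm(10), g3 = rnorm(10) + 5)
  r <- anova_tukey(base)
  expect_lt(r$p, 0.001)
  sig <- r$tukey$significant
  names(sig) <- r$tukey$comparison
  expect_true(sig[["g3-g1"]])
  expect_true(sig[["g3-g2"]])
  expect_false(sig[["g2-g1"]])

  same <- anova_tukey(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_equal(same$F, 0)

  eqgrp <- anova_tukey(list(a = rnorm(10), b = rnorm(10)))
  expect_false(any(eqgrp$tukey$significant) && eqgrp$p < 0.001)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni_adjust(c(0.9, 0.9)), c(1, 1))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("IQR uses linear-interpolation quantiles", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8)
  q <- iqr_stats(v)
  expect_equal(q$q1, quantile(v, 0.25, names = FALSE))
  expect_equal(q$iqr, q$q3 - q$q1)
  expect_gte(q$iqr, 0)
})
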