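chi2_direct <- function(m) {
  # independent textbook computation: sum (O-E)^2 / E
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

test_that("Pearson chi-square matches the direct formula and closed forms", {
  tab <- contingency_table(rbind(c(15, 3, 2), c(0, 1, 19)),
                           groups = c("treatment", "control"),
                           outcomes = c("fully", "partially", "not"))
  res <- chi_square_independence(tab)
  expect_equal(unname(res$statistic), chi2_direct(unclass(tab)), tolerance = 1e-12)
  expect_equal(unname(res$statistic), 2 * (7.5 + 0.5 + 72.25 / 10.5),
               tolerance = 1e-12)  # = 29.7619 on the observed outcome table
  expect_lt(res$p.value, 1e-4)
  expect_equal(res$df, 2)
  # adjusted standardized residual of the fully-lifted treatment cell
  expect_equal(res$residuals[1, 1],
               7.5 / sqrt(7.5 * (1 - 0.5) * (1 - 15 / 40)), tolerance = 1e-12)
  expect_equal(dim(res$residual_p), dim(tab))
  expect_true(all(res$residual_p >= 0 & res$residual_p <= 1))
  # 2x2 diagonal table: N(ad-bc)^2 / (r1 r2 c1 c2)
  res22 <- chi_square_independence(rbind(c(10, 0), c(0, 10)))
  expect_equal(unname(res22$statistic), 20, tolerance = 1e-12)
  # identical rows: independence exactly
  resid0 <- chi_square_independence(rbind(c(4, 6, 2), c(4, 6, 2)))
  expect_equal(unname(resid0$statistic), 0)
  expect_equal(resid0$p.value, 1)
  expect_error(chi_square_independence(rbind(c(1, 0), c(2, 0))), "marginal")
})

test_that("chi-square is invariant under row and column permutation", {
  set.seed(9)
  for (rep in 1:4) {
    m <- matrix(rpois(6, 8) + 1, 2, 3)
    a <- unname(chi_square_independence(m)$statistic)
    expect_equal(unname(chi_square_independence(m[2:1, ])$statistic), a)
    expect_equal(unname(chi_square_independence(m[, c(3, 1, 2)])$statistic), a)
  }
})

test_that("Wald binomial intervals follow p-hat +/- z sqrt(p(1-p)/n)", {
  ci <- wald_binomial_ci(15, 20)
  expect_equal(ci$estimate, 0.75)
  expect_equal(ci$margin, 1.959964 * sqrt(0.75 * 0.25 / 20), tolerance = 1e-6)
  expect_equal(ci$margin, 0.18977, tolerance = 1e-4)
  # degenerate p-hat: zero-width interval
  ci0 <- wald_binomial_ci(0, 20)
  expect_equal(c(ci0$lower, ci0$upper), c(0, 0))
  # symmetry about 1/2
  ci5 <- wald_binomial_ci(10, 20)
  expect_equal(ci5$lower + ci5$upper, 1)
  expect_error(wald_binomial_ci(21, 20))
})

test_that("bootstrap median CI: trivial cases and enumeration oracle", {
  # constant data: degenerate interval at the constant
  cc <- bootstrap_median_ci(rep(4.2, 9), B = 500, seed = 1)
  expect_equal(c(cc$lower, cc$upper), c(4.2, 4.2))
  # the sample median lies inside its own interval
  ci <- bootstrap_median_ci(1:1000, B = 2000, seed = 2)
  expect_true(ci$lower <= 500.5 && 500.5 <= ci$upper)
  # exhaustive enumeration of all n^n resamples at n = 5
  x <- c(2.1, 3.5, 4.0, 7.2, 9.9)
  idx <- as.matrix(expand.grid(rep(list(1:5), 5)))
  all_meds <- apply(matrix(x[idx], nrow(idx), 5), 1, median)
  enum <- unname(quantile(all_meds, c(0.025, 0.975)))
  bs <- bootstrap_median_ci(x, B = 20000, seed = 7)
  expect_equal(c(bs$lower, bs$upper), enum, tolerance = 1e-12)
  # bit-reproducible under a fixed seed
  set.seed(99); xx <- rnorm(30)
  expect_identical(bootstrap_median_ci(xx, B = 200, seed = 5),
                   bootstrap_median_ci(xx, B = 200, seed = 5))
})

test_that("permutation Mann-Whitney matches exhaustive enumeration", {
  # identical samples: every permutation is as extreme
  expect_equal(mann_whitney_permutation(c(5, 7, 3), c(5, 7, 3))$p.value, 1)
  # textbook separation case: 2 of the 6 assignments are as extreme
  r <- mann_whitney_permutation(c(1, 2), c(3, 4))
  expect_equal(r$p.value, 2 / 6, tolerance = 1e-12)
  expect_true(r$exhaustive)
  # ties handled by midranks; U agrees with independent pair counting
  x <- c(1, 1, 2); y <- c(1, 2, 2)
  rt <- mann_whitney_permutation(x, y)
  expect_equal(unname(rt$statistic), u_pair_count(x, y))
  # independent enumeration oracle on random tied instances (n <= 10)
  set.seed(31)
  for (rep in 1:4) {
    x <- sample(1:4, 5, replace = TRUE); y <- sample(1:4, 5, replace = TRUE)
    res <- mann_whitney_permutation(x, y)
    pool <- c(x, y); mu <- length(x) * length(y) / 2
    u_obs <- u_pair_count(x, y)
    us <- apply(combn(10, 5), 2, function(ix)
      u_pair_count(pool[ix], pool[-ix]))
    p_exh <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    expect_equal(res$p.value, p_exh, tolerance = 1e-12)
    expect_equal(unname(res$statistic), u_obs)
  }
  # random-permutation branch sits within Monte-Carlo error of exhaustive
  x <- c(1, 3, 3, 6, 7, 9); y <- c(2, 3, 5, 8, 8, 12)
  p_exh <- mann_whitney_permutation(x, y)$p.value
  p_mc <- mann_whitney_permutation(x, y, n_perm = 4000, seed = 1,
                                   exhaustive_limit = 1)$p.value
  se <- sqrt(p_exh * (1 - p_exh) / 4000)
  expect_lt(abs(p_mc - p_exh), 3 * se + 1 / 4000)
})

test_that("Levene's test (center = mean) matches an independent ANOVA route", {
  # identical multisets: F = 0
  expect_equal(unname(levene_test(c(1, 4, 6), c(6, 1, 4))$statistic), 0)
  # direction: wider group drives F > 0
  expect_gt(unname(levene_test(c(0, 2), c(-5, 5))$statistic), 0)
  expect_error(levene_test(c(2, 2), c(3, 3)), "degenerate")
  set.seed(17)
  for (rep in 1:3) {
    x <- rnorm(12, sd = 1); y <- rnorm(15, sd = 2)
    res <- levene_test(x, y)
    # oracle 1: two-pass ANOVA on absolute deviations via lm/anova
    ad <- c(abs(x - mean(x)), abs(y - mean(y)))
    gr <- factor(rep(1:2, c(12, 15)))
    f_lm <- anova(lm(ad ~ gr))$`F value`[1]
    expect_equal(unname(res$statistic), f_lm, tolerance = 1e-10)
    expect_equal(res$df, c(1, 25))
    # oracle 2: car's implementation with the mean center
    if (requireNamespace("car", quietly = TRUE)) {
      f_car <- car::leveneTest(c(x, y), gr, center = mean)$`F value`[1]
      expect_equal(unname(res$statistic), f_car, tolerance = 1e-10)
    }
  }
})

test_that("regression through the origin and its free-intercept comparison", {
  # exact proportionality
  x <- 1:10; y <- 2 * x
  r <- suppressWarnings(regression_through_origin(x, y))  # lm: perfect fit
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_gt(r$r.squared, 1 - 1e-12)
  # slope equals closed form on noisy data
  set.seed(5)
  x <- runif(40, 1, 5); y <- 3 * x + rnorm(40)
  r <- regression_through_origin(x, y)
  expect_equal(r$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
  expect_equal(r$df, c(1, 39))
  # a true nonzero intercept is detected by the model comparison
  y10 <- x + 10 + rnorm(40, sd = 0.5)
  r10 <- regression_through_origin(x, y10)
  expect_lt(r10$free$anova_p, 0.05)
  expect_gt(r10$free$intercept_ci[1], 0)   # CI excludes zero
  # and with a true zero intercept the CI covers zero
  y0 <- 2 * x + rnorm(40, sd = 0.5)
  r0 <- regression_through_origin(x, y0)
  expect_lt(r0$free$intercept_ci[1], 0)
  expect_gt(r0$free$intercept_ci[2], 0)
  expect_error(regression_through_origin(c(0, 0), c(1, 2)), "rank deficiency")
})
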