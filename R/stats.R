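#' Contingency table of lift outcomes
#'
#' Integer counts of outcomes (columns) by treatment group (rows), e.g.
#' fully/partially/not lifted by treatment/control.
#'
#' @param counts Integer matrix (>= 2 rows and columns, non-negative,
#'   positive grand total).
#' @param groups,outcomes Optional dimension labels.
#' @return A `contingency_table` (an integer matrix with dimnames).
#' @export
contingency_table <- function(counts,
                              groups = rownames(counts),
                              outcomes = colnames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) <= 0) stop("grand total must be positive", call. = FALSE)
  if (is.null(groups)) groups <- paste0("group", seq_len(nrow(counts)))
  if (is.null(outcomes)) outcomes <- paste0("outcome", seq_len(ncol(counts)))
  structure(counts, dimnames = list(groups, outcomes),
            class = c("contingency_table", "matrix"))
}

#' @export
print.contingency_table <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

new_et_test <- function(method, ...) {
  structure(c(list(method = method), list(...)), class = "et_test")
}

#' @export
print.et_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic))
    cat(sprintf("  %s = %.4g", names(x$statistic)[1] %||% "stat", x$statistic), "")
  if (!is.null(x$df)) cat(sprintf(" df = %s", paste(x$df, collapse = ",")), "")
  if (!is.null(x$p.value)) cat(sprintf(" p = %.4g", x$p.value))
  cat("\n")
  if (!is.null(x$conf.int))
    cat(sprintf("  95%% CI [%.4g, %.4g]\n", x$conf.int[1], x$conf.int[2]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson chi-square test of independence with adjusted residuals
#'
#' Pearson chi-square on an r x c table with asymptotic p-value, plus
#' per-cell adjusted standardized residuals
#' (O - E) / sqrt(E (1 - row_total/N)(1 - col_total/N)) and their
#' Bonferroni-corrected two-sided normal p-values (corrected over the r*c
#' cells). Used post hoc to locate which outcome/group cells drive a
#' significant overall test.
#'
#' @param table A [contingency_table()] or plain count matrix.
#' @return An `et_test` with `statistic`, `df`, `p.value`, `expected`,
#'   `residuals` (adjusted) and `residual_p` (Bonferroni-corrected).
#' @export
chi_square_independence <- function(table) {
  m <- unclass(as.matrix(table))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: zero marginal", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  adj <- ct$stdres   # (O-E)/sqrt(E(1-rp)(1-cp)) -- the adjusted residuals
  cells <- length(m)
  res_p <- adj
  res_p[] <- pmin(1, 2 * pnorm(-abs(adj)) * cells)
  new_et_test("Pearson chi-square test of independence",
              statistic = c("X-squared" = unname(ct$statistic)),
              df = unname(ct$parameter),
              p.value = unname(ct$p.value),
              N = sum(m),
              expected = ct$expected,
              residuals = adj,
              residual_p = res_p)
}

#' Wald binomial confidence interval
#'
#' p-hat +/- z sqrt(p-hat (1 - p-hat) / n) with z = 1.959964 at the 95%
#' level.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n > 0`.
#' @param level Confidence level.
#' @return `list(estimate, lower, upper, margin)` on the proportion scale.
#' @export
wald_binomial_ci <- function(successes, n, level = 0.95) {
  stopifnot(n > 0, successes >= 0, successes <= n)
  p <- successes / n
  z <- qnorm(1 - (1 - level) / 2)
  margin <- z * sqrt(p * (1 - p) / n)
  list(estimate = p, lower = p - margin, upper = p + margin, margin = margin)
}

#' Bootstrap percentile confidence interval of the median
#'
#' Percentile interval of `B` resampled medians; bit-reproducible under a
#' fixed seed.
#'
#' @param x Numeric data, non-empty.
#' @param B Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed (optional).
#' @return `list(median, lower, upper, B)`.
#' @export
bootstrap_median_ci <- function(x, B = 10000L, level = 0.95, seed = NULL) {
  stopifnot(length(x) > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  sm <- matrix(x[idx], n, B)
  meds <- apply(sm, 2, median)
  a <- (1 - level) / 2
  ci <- unname(quantile(meds, c(a, 1 - a)))
  list(median = median(x), lower = ci[1], upper = ci[2], B = B)
}

mw_u_statistic <- function(x, y) {
  # Mann-Whitney U of the first sample, with average (mid-) ranks for ties
  n1 <- length(x)
  rk <- rank(c(x, y))
  sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Permutation Mann-Whitney U test
#'
#' Mann-Whitney U with midranks for ties; the two-tailed p-value is the
#' proportion of label permutations whose |U - n1 n2 / 2| is at least the
#' observed one, the observed permutation included (so p is never 0). When
#' the number of distinct group assignments is at most `exhaustive_limit`
#' all of them are enumerated; otherwise `n_perm` random permutations are
#' drawn.
#'
#' @param x,y Numeric samples, non-empty.
#' @param n_perm Random permutation count when not exhaustive.
#' @param seed Integer seed for the random-permutation branch.
#' @param exhaustive_limit Enumeration cutoff on choose(n1+n2, n1).
#' @return An `et_test` with `statistic` (W = U of sample 1), `p.value`,
#'   `n_perm` and `exhaustive` flag.
#' @export
mann_whitney_permutation <- function(x, y, n_perm = 10000L, seed = NULL,
                                     exhaustive_limit = 20000) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  const <- n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  u_obs <- sum(rk[seq_len(n1)]) - const
  t_obs <- abs(u_obs - mu) - 1e-9   # tolerance so ties in |U - mu| count
  n_arrangements <- choose(n, n1)
  if (n_arrangements <= exhaustive_limit) {
    sets <- combn(n, n1)
    us <- colSums(matrix(rk[sets], nrow = n1)) - const
    p <- mean(abs(us - mu) >= t_obs)
    return(new_et_test("Mann-Whitney U test (exhaustive permutation p)",
                       statistic = c(W = u_obs), p.value = p,
                       n_perm = ncol(sets), exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    ub <- sum(rk[sample.int(n, n1)]) - const
    if (abs(ub - mu) >= t_obs) hits <- hits + 1L
  }
  p <- (hits + 1) / (n_perm + 1)
  new_et_test("Mann-Whitney U test (random permutation p)",
              statistic = c(W = u_obs), p.value = p,
              n_perm = n_perm, exhaustive = FALSE)
}

#' Levene's test for equality of variances
#'
#' Classical Levene form: one-way ANOVA F on the absolute deviations from
#' the group means, with (1, n - 2) degrees of freedom for two groups.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @return An `et_test` with `statistic` (F), `df` and `p.value`.
#' @export
levene_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  ax <- abs(x - mean(x)); ay <- abs(y - mean(y))
  if (all(c(ax, ay) == 0))
    stop("degenerate: zero within-group deviation in all groups", call. = FALSE)
  n1 <- length(ax); n2 <- length(ay); n <- n1 + n2
  gm <- mean(c(ax, ay))
  ssb <- n1 * (mean(ax) - gm)^2 + n2 * (mean(ay) - gm)^2
  ssw <- sum((ax - mean(ax))^2) + sum((ay - mean(ay))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  new_et_test("Levene's test (center = mean)",
              statistic = c(F = f), df = c(1, n - 2),
              p.value = pf(f, 1, n - 2, lower.tail = FALSE))
}

#' Regression through the origin with free-intercept comparison
#'
#' Least-squares fit of y = b x (slope sum(xy)/sum(x^2)), with the
#' uncentered R-squared and overall F on (1, n-1) degrees of freedom that
#' are standard for forced-origin models, plus the free-intercept fit
#' y = a + b x, its intercept confidence interval, and the ANOVA comparison
#' between the two models.
#'
#' @param x,y Numeric vectors (>= 2 points, not all x equal).
#' @param level Confidence level for the intercept interval.
#' @return A list: `slope`, `r.squared`, `fstatistic`, `df`, `p.value`,
#'   `free` (intercept, intercept_ci, slope, anova_p), and the two `lm`
#'   fits.
#' @export
regression_through_origin <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (all(x == 0) || length(unique(x)) < 1 || sum(x^2) == 0)
    stop("rank deficiency: sum(x^2) is zero", call. = FALSE)
  fit0 <- lm(y ~ 0 + x)
  fit1 <- lm(y ~ x)
  s0 <- summary(fit0)
  fs <- s0$fstatistic
  cmp <- anova(fit0, fit1)
  ci <- confint(fit1, "(Intercept)", level = level)
  list(slope = unname(coef(fit0)[1]),
       r.squared = s0$r.squared,
       fstatistic = unname(fs[1]),
       df = unname(fs[2:3]),
       p.value = pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
       free = list(intercept = unname(coef(fit1)[1]),
                   intercept_ci = unname(ci[1, ]),
                   slope = unname(coef(fit1)[2]),
                   anova_p = cmp$`Pr(>F)`[2]),
       fit_zero = fit0, fit_free = fit1)
}
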