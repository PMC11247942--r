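test_that("Fisher exact test reproduces enumerated two-sided p-values and odds ratios", {
  res <- fisher_exact_2x2(c(3, 1, 1, 3))
  expect_equal(res$p_value, 34 / 70, tolerance = 1e-12)
  expect_equal(res$estimate, 9)

  res <- fisher_exact_2x2(c(5, 5, 5, 5))
  expect_equal(res$p_value, 1)
  expect_equal(res$estimate, 1)

  res <- fisher_exact_2x2(c(10, 0, 0, 10))
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # Haldane correction keeps the estimate finite for a perfect-overlap table
  expect_true(is.finite(res$estimate) && res$estimate > 1)

  expect_error(fisher_exact_2x2(c(0, 0, 0, 0)), "degenerate")
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "non-negative")
})

test_that("Fisher exact test matches brute-force enumeration and fisher.test on random tables", {
  set.seed(71)
  for (i in 1:200) {
    tab <- random_table(60)
    if (sum(tab) == 0) next
    p_pkg <- fisher_exact_2x2(tab)$p_value
    p_oracle <- oracle_fisher_p(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p_pkg, p_oracle, tolerance = 1e-9)
  }
  # spot cross-check against the independent base-R implementation
  for (tab in list(c(8, 2, 4, 6), c(1, 9, 11, 3), c(12, 0, 5, 7))) {
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Yates-corrected chi-squared reproduces the repair-panel contrast and base R", {
  # counts reconstructed from the printed group fractions: 52% of 104, 34% of 260
  res <- chi2_yates(c(54, 50, 88, 172))
  expect_equal(round(res$p_value, 3), 0.002)
  ref <- suppressWarnings(stats::chisq.test(matrix(c(54, 50, 88, 172), 2, byrow = TRUE)))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)

  res <- chi2_yates(c(10, 10, 10, 10))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # continuity-corrected arithmetic by hand: all E = 12.5, |O - E| = 7.5
  res <- chi2_yates(c(20, 5, 5, 20))
  expect_equal(res$statistic, 4 * (7.5 - 0.5)^2 / 12.5, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(4 * 49 / 12.5, 1, lower.tail = FALSE))

  expect_error(chi2_yates(c(0, 0, 5, 5)), "margin")
})

test_that("Benjamini-Hochberg adjustment is correct and monotone in rank", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))
    # non-decreasing in rank, bounded by 1
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj >= p - 1e-15 & adj <= 1))
  }
  # step-up on a fully tied block is a fixed point
  expect_equal(bh_adjust(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
})

test_that("weighted t-test handles degenerate inputs and reduces to Welch with unit weights", {
  res <- weighted_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  res <- weighted_ttest(c(2, 2), c(1, 1))
  expect_equal(res$estimate, 1)
  expect_equal(res$p_value, 0)  # both variances zero, means differ

  set.seed(9)
  for (i in 1:30) {
    x1 <- stats::rnorm(sample(3:40, 1), sd = stats::runif(1, 0.5, 3))
    x0 <- stats::rnorm(sample(3:40, 1), mean = stats::runif(1, -1, 1))
    ref <- stats::t.test(x1, x0)
    res <- weighted_ttest(x1, x0)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(res$df, unname(ref$parameter), tolerance = 1e-10)
  }
})

test_that("weighted t-test is invariant to rescaling all weights", {
  set.seed(13)
  x1 <- stats::rnorm(25)
  x0 <- stats::rnorm(30, 0.4)
  w1 <- stats::runif(25, 0.1, 1)
  w0 <- stats::runif(30, 0.1, 1)
  a <- weighted_ttest(x1, x0, w1, w0)
  b <- weighted_ttest(x1, x0, 7 * w1, 7 * w0)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_error(weighted_ttest(x1, x0, rep(0, 25), w0), "weight")
})

test_that("standardized difference follows its conventions", {
  expect_equal(standardized_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  x1 <- stats::rnorm(2000, 1, 1)
  x0 <- stats::rnorm(2000, 0, 1)
  expect_equal(standardized_difference(x1, x0), 100, tolerance = 8)
  # weight-scale invariance
  set.seed(3)
  v1 <- stats::rnorm(40); v0 <- stats::rnorm(40, 0.5)
  w1 <- stats::runif(40); w0 <- stats::runif(40)
  expect_equal(standardized_difference(v1, v0, w1, w0),
               standardized_difference(v1, v0, 3 * w1, 3 * w0), tolerance = 1e-12)
  # binary covariates use p(1-p)
  b1 <- rep(c(1, 0), c(6, 4))
  b0 <- rep(c(1, 0), c(2, 8))
  expect_equal(standardized_difference(b1, b0),
               100 * 0.4 / sqrt((0.6 * 0.4 + 0.2 * 0.8) / 2), tolerance = 1e-12)
  # both variances zero
  expect_equal(standardized_difference(c(1, 1), c(1, 1)), 0)
  expect_equal(standardized_difference(c(2, 2), c(1, 1), binary = FALSE), Inf)
})

test_that("logistic MLE matches closed forms and glm", {
  # intercept-only closed form
  y <- rep(c(1, 0), c(30, 70))
  fit <- logistic_mle(matrix(1, 100, 1), y)
  expect_equal(unname(fit$coefficients), log(30 / 70), tolerance = 1e-8)
  expect_equal(fit$aic, 2 - 2 * fit$log_likelihood)

  # saturated 2x2 closed form: slope log(6)
  x <- cbind(1, rep(c(1, 0), c(10, 10)))
  y <- c(rep(c(1, 0), c(8, 2)), rep(c(1, 0), c(4, 6)))
  fit <- logistic_mle(x, y)
  expect_equal(unname(fit$coefficients[2]), log(6), tolerance = 1e-7)

  # general agreement with glm (coefficients, SEs, logLik)
  set.seed(21)
  x1 <- stats::rnorm(200); x2 <- stats::rbinom(200, 1, 0.4)
  y <- stats::rbinom(200, 1, stats::plogis(-0.5 + 0.7 * x1 - 0.4 * x2))
  fit <- logistic_mle(cbind(1, x1, x2), y)
  ref <- stats::glm(y ~ x1 + x2, family = stats::binomial())
  # glm stops on deviance change; agreement is to its convergence precision
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$standard_errors),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)
  expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$aic, stats::AIC(ref), tolerance = 1e-6)
})

test_that("logistic MLE recovers simulated coefficients and sits at a local maximum", {
  set.seed(33)
  x <- stats::rnorm(500)
  y <- stats::rbinom(500, 1, stats::plogis(-1 + 0.8 * x))
  fit <- logistic_mle(cbind(1, x), y)
  expect_true(all(abs(fit$coefficients - c(-1, 0.8)) < 2 * fit$standard_errors))

  ll_at <- function(beta) {
    p <- stats::plogis(drop(cbind(1, x) %*% beta))
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  for (i in 1:20) {
    pert <- stats::rnorm(2)
    pert <- pert / sqrt(sum(pert^2)) * 0.01
    expect_lte(ll_at(fit$coefficients + pert), fit$log_likelihood + 1e-12)
  }
})

test_that("logistic MLE flags separation and names collinear columns", {
  set.seed(41)
  x <- stats::rnorm(60)
  y <- as.numeric(x > 0)
  expect_warning(fit <- logistic_mle(cbind(1, x), y), "separation")
  expect_false(fit$converged)
  expect_true(fit$separated)

  x2 <- cbind(`(Intercept)` = 1, a = x, twice_a = 2 * x)
  expect_error(logistic_mle(x2, stats::rbinom(60, 1, 0.5)), "twice_a")
})

test_that("Tjur R2 follows its definition and is order-invariant", {
  expect_equal(tjur_r2(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(tjur_r2(rep(0.3, 10), rep(c(1, 0), 5)), 0)
  expect_equal(tjur_r2(c(0.8, 0.6, 0.2, 0.4), c(1, 1, 0, 0)), 0.4)
  set.seed(2)
  p <- stats::runif(50)
  y <- stats::rbinom(50, 1, p)
  if (length(unique(y)) == 2) {
    o <- sample(50)
    expect_equal(tjur_r2(p, y), tjur_r2(p[o], y[o]))
  }
  expect_error(tjur_r2(c(0.2, 0.4), c(1, 1)), "single class")
})
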