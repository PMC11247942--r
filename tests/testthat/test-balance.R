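spec4 <- propensity_spec(c("age", "gender", "bmi", "tumor_size"))

test_that("matching weights follow the MW formula and its invariants", {
  expect_equal(matching_weights(0.5, "CR"), 1)
  expect_equal(matching_weights(0.5, "ICR"), 1)
  expect_equal(matching_weights(0.8, "CR"), 0.25)
  expect_equal(matching_weights(0.8, "ICR"), 1)
  expect_error(matching_weights(c(0.2, 1), c("CR", "ICR")), "strictly inside")

  set.seed(8)
  e <- stats::runif(500, 0.01, 0.99)
  g <- sample(c("CR", "ICR"), 500, replace = TRUE)
  w <- matching_weights(e, g)
  expect_true(all(w > 0 & w <= 1))
  # weight is exactly 1 on a sample's minority-probability side
  expect_true(all(w[g == "CR" & e < 0.5] == 1))
  expect_true(all(w[g == "ICR" & e > 0.5] == 1))
})

test_that("propensity fit handles uninformative covariates and detects confounding", {
  sim <- simulate_cohort(simulation_preset("strong-confounding", seed = 17))
  pf <- fit_propensity(sim$clinical, spec4)
  auc <- {
    y <- sim$clinical$response[pf$kept] == "CR"
    r <- rank(pf$scores)
    (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
  }
  expect_gt(auc, 0.6)  # confounded assignment is learnable

  # a constant covariate carries no information: scores collapse to prevalence
  cl <- sim$clinical
  cl$flat <- 1
  pf0 <- suppressMessages(fit_propensity(cl, propensity_spec("flat")))
  expect_equal(unname(pf0$scores), rep(mean(cl$response == "CR"), nrow(cl)),
               tolerance = 1e-8)

  expect_error(propensity_spec(character(0)), "non-empty")
})

test_that("balance report equals the unweighted diagnostics under unit weights", {
  sim <- simulate_cohort(simulation_preset("paperlike", seed = 5))
  rep1 <- balance_report(sim$clinical, rep(1, nrow(sim$clinical)), spec4)
  expect_equal(rep1$before, rep1$after)
  # a known imbalance: means 1 vs 0 with unit variances reads 100%
  cl <- data.frame(sample_id = sprintf("S%03d", 1:400),
                   response = rep(c("CR", "ICR"), each = 200),
                   x = c(stats::rnorm(200, 1), stats::rnorm(200, 0)))
  r <- balance_report(cl, rep(1, 400), propensity_spec("x"))
  expect_equal(r$before, 100, tolerance = 15)
})

test_that("balance iteration converges immediately on a randomized cohort", {
  sim <- simulate_cohort(simulation_preset("null", seed = 23))
  bc <- suppressMessages(iterate_balance(sim$clinical, spec4))
  expect_true(bc$converged)
  expect_equal(bc$iterations_used, 1)
  expect_true(all(bc$report$after < 10))
})

test_that("nonlinear confounding triggers model augmentation before converging", {
  sim <- simulate_cohort(simulation_preset(
    "strong-confounding", seed = 48, n_cr = 34L, n_icr = 86L,
    assignment_coefficients = c(age = 1.5, bmi = -0.8, gender = 0.5, tumor_size = -0.8),
    assignment_quadratic = c(age = 2.0, bmi = 0, gender = 0, tumor_size = 0)))
  bc <- suppressMessages(iterate_balance(sim$clinical, spec4))
  expect_true(bc$converged)
  expect_gte(bc$iterations_used, 2)
  expect_true(any(grepl("\\^2", bc$final_terms)))
  # after convergence, every weighted standardized difference is under threshold
  expect_true(all(bc$report$after < 10))
})

test_that("an unreachable balance criterion is reported, not silenced", {
  sim <- simulate_cohort(simulation_preset("strong-confounding", seed = 2))
  expect_warning(
    bc <- suppressMessages(iterate_balance(sim$clinical, spec4, threshold = 0,
                                           max_iter = 3)),
    "did not reach")
  expect_false(bc$converged)
  expect_equal(bc$iterations_used, 3)
})

test_that("weighting leaves a randomized cohort's TMB contrast unchanged", {
  devs <- replicate(10, {
    s <- sample.int(1e6, 1)
    sim <- simulate_cohort(simulation_preset("null", seed = s))
    f <- suppressMessages(filter_variants(sim$maf))
    tmb <- compute_tmb(f, sim$clinical$sample_id)
    g <- sim$clinical$response
    naive <- mean(tmb[g == "CR"]) - mean(tmb[g == "ICR"])
    bc <- suppressMessages(suppressWarnings(iterate_balance(sim$clinical, spec4)))
    w <- compare_tmb_weighted(tmb[match(bc$sample_ids, names(tmb))],
                              bc$group, bc$matching_weights)$estimate
    w - naive
  })
  expect_lt(mean(abs(devs)), 0.02)  # mutations/Mb; null contrast is ~0.3 in scale
})

test_that("weighted TMB comparison reduces to Welch under equal weights and errors on tiny groups", {
  set.seed(12)
  tmb <- stats::rlnorm(60, -1, 0.4)
  g <- rep(c("CR", "ICR"), each = 30)
  res <- compare_tmb_weighted(tmb, g, rep(1, 60))
  ref <- stats::t.test(tmb[g == "CR"], tmb[g == "ICR"])
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(res$estimate, unname(diff(rev(tapply(tmb, g, mean)))), tolerance = 1e-12)
  expect_error(compare_tmb_weighted(tmb, g, c(1, rep(0, 29), rep(1, 30))), "positive weight")
})

test_that("matching-weight balancing recovers a confounded TMB effect", {
  # planted burden difference of 4 mutations with age-driven confounding strong
  # enough to bias the naive contrast by more than half the true effect
  reps <- 200
  out <- vapply(seq_len(reps), function(i) {
    sim <- simulate_cohort(simulation_preset(
      "strong-confounding", seed = 40000 + i,
      assignment_coefficients = c(age = 1.2, bmi = -0.7, gender = 0.5, tumor_size = -0.7),
      tmb_age_coef = 0.6))
    f <- suppressMessages(filter_variants(sim$maf))
    tmb <- compute_tmb(f, sim$clinical$sample_id)
    g <- sim$clinical$response
    naive <- mean(tmb[g == "CR"]) - mean(tmb[g == "ICR"])
    bc <- suppressMessages(suppressWarnings(iterate_balance(sim$clinical, spec4)))
    w <- compare_tmb_weighted(tmb[match(bc$sample_ids, names(tmb))],
                              bc$group, bc$matching_weights)$estimate
    c(naive = naive, weighted = w)
  }, numeric(2))
  delta <- (14 - 10) * exp(0.6^2 / 2) / 38  # marginal causal contrast, mutations/Mb
  # the scenario's premise: naive bias exceeds half the planted effect
  expect_gt(mean(abs(out["naive", ] - delta)), delta / 2)
  closer <- abs(out["weighted", ] - delta) < abs(out["naive", ] - delta)
  expect_gte(mean(closer), 0.9)
})
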