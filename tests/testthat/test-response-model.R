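fake_screening <- function(genes = character(0), pairs = NULL) {
  structure(list(
    genes = data.frame(gene = genes, odds_ratio = rep(2, length(genes)),
                       p = rep(0.01, length(genes)), stringsAsFactors = FALSE),
    pairs = if (is.null(pairs)) {
      data.frame(gene_a = character(0), gene_b = character(0),
                 odds_ratio = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
    } else pairs,
    alpha_screen = 0.1, treated = "CR", direction = "any"),
    class = "screening_result")
}

test_that("screening retains factors by p-value with optional CR-direction filter", {
  m <- as_mutmat(matrix(0L, 200, 3), genes = c("FLAT", "UP", "DOWN"))
  resp <- rep(c("CR", "ICR"), each = 100)
  m[c(1:30, 101:130), "FLAT"] <- 1L            # identical frequency: p = 1
  m[c(1:50, 101:115), "UP"] <- 1L              # CR-enriched
  m[c(1:10, 101:150), "DOWN"] <- 1L            # ICR-enriched
  ints <- data.frame(gene_a = "FLAT", gene_b = "UP", stringsAsFactors = FALSE)

  scr <- screen_predictors(m, ints, resp)
  expect_false("FLAT" %in% scr$genes$gene)
  expect_true(all(scr$genes$p < 0.1))
  expect_true("DOWN" %in% scr$genes$gene)

  scr_cr <- screen_predictors(m, ints, resp, direction = "CR")
  expect_false("DOWN" %in% scr_cr$genes$gene)

  # alpha_screen = 1 retains everything offered
  scr_all <- screen_predictors(m, ints, resp, alpha_screen = 1)
  expect_equal(nrow(scr_all$genes), 3)
  expect_equal(nrow(scr_all$pairs), 1)

  expect_warning(screen_predictors(m[, "FLAT", drop = FALSE], NULL, resp),
                 "no gene or pair")
})

test_that("screening has power for planted CR-enriched genes", {
  set.seed(55)
  resp <- rep(c("CR", "ICR"), c(101, 229))
  p_icr <- 0.15
  p_cr <- stats::plogis(stats::qlogis(p_icr) + log(3))
  retained <- replicate(100, {
    m <- sapply(1:10, function(j) {
      stats::rbinom(330, 1, ifelse(resp == "CR", p_cr, p_icr))
    })
    m <- as_mutmat(m, genes = sprintf("PG%02d", 1:10))
    nrow(suppressWarnings(screen_predictors(m, NULL, resp))$genes)
  })
  expect_gte(mean(retained), 8)
})

test_that("feature construction maps pair counts onto the published categories", {
  cl <- data.frame(
    sample_id = sprintf("S%d", 1:5), response = c("CR", "CR", "ICR", "ICR", "ICR"),
    tumor_size = c(4, 5, 6, NA, 3), ajcc_stage = c("2", "3", "3", "2", "2"),
    stringsAsFactors = FALSE)
  m <- as_mutmat(matrix(0L, 5, 6), samples = cl$sample_id,
                 genes = c("A", "B", "C", "D", "E", "F"))
  m[1, ] <- 1L                        # S1 carries every pair: count 3
  m[2, c("A", "B", "C", "D")] <- 1L   # S2: pairs AB and CD: count 2
  m[3, c("A", "C")] <- 1L             # S3: no complete pair
  pairs <- data.frame(gene_a = c("A", "C", "E"), gene_b = c("B", "D", "F"),
                      odds_ratio = 3, p = 0.01, stringsAsFactors = FALSE)
  ft <- suppressMessages(build_features(cl, m, fake_screening("A", pairs)))
  expect_equal(nrow(ft), 4)                       # missing tumor size dropped
  expect_equal(attr(ft, "n_dropped"), 1)
  expect_equal(ft$pair_count, c(3L, 2L, 0L, 0L))
  expect_equal(as.character(ft$cooccurrence_category),
               c("3 or more", "1-2", "0", "0"))
  expect_equal(ft$network_gene_mutated, c(1L, 1L, 1L, 0L))
  # no screened gene mutated -> indicator 0 everywhere
  ft0 <- suppressMessages(build_features(cl, m, fake_screening(character(0), pairs)))
  expect_true(all(ft0$network_gene_mutated == 0))
})

test_that("response model matches glm, reports Wald ORs, and runs the LRT identity", {
  set.seed(77)
  n <- 300
  ft <- data.frame(
    sample_id = sprintf("S%03d", 1:n),
    tumor_size = stats::rlnorm(n, log(4.5), 0.3),
    ajcc_stage = factor(sample(c("2", "3"), n, TRUE), levels = c("2", "3")),
    network_gene_mutated = stats::rbinom(n, 1, 0.4),
    pair_count = stats::rbinom(n, 5, 0.25))
  ft$cooccurrence_category <- cut(ft$pair_count, c(-Inf, 0, 2, Inf),
                                  labels = c("0", "1-2", "3 or more"))
  lp <- -0.8 - 0.24 * ft$tumor_size + 0.9 * ft$network_gene_mutated +
    0.5 * (ft$cooccurrence_category == "1-2") +
    2.1 * (ft$cooccurrence_category == "3 or more")
  ft$response <- stats::rbinom(n, 1, stats::plogis(lp))

  fit <- fit_response_model(ft, "categorical")
  ref <- stats::glm(response ~ tumor_size + I(ajcc_stage == "3") +
                      network_gene_mutated + I(cooccurrence_category == "1-2") +
                      I(cooccurrence_category == "3 or more"),
                    data = ft, family = stats::binomial())
  expect_equal(unname(fit$fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$aic, stats::AIC(ref), tolerance = 1e-6)
  expect_equal(fit$coef_table$odds_ratio, exp(fit$coef_table$estimate))
  expect_equal(fit$coef_table$ci_high,
               exp(fit$coef_table$estimate + stats::qnorm(0.975) * fit$coef_table$std_error))

  # LRT identity: statistic equals twice the log-likelihood gap of the nested refit
  red <- stats::glm(response ~ tumor_size + I(ajcc_stage == "3") + network_gene_mutated,
                    data = ft, family = stats::binomial())
  expect_gte(fit$lrt$statistic, 0)
  expect_equal(fit$lrt$statistic,
               2 * (as.numeric(stats::logLik(ref)) - as.numeric(stats::logLik(red))),
               tolerance = 1e-6)
  expect_equal(fit$lrt$df, 2)

  # constant tumor size is a named rank error
  ft2 <- ft
  ft2$tumor_size <- 5
  expect_error(fit_response_model(ft2, "categorical"), "tumor_size")
})

test_that("a null cohort yields negligible discrimination", {
  set.seed(99)
  tjurs <- replicate(20, {
    n <- 200
    ft <- data.frame(
      sample_id = sprintf("S%03d", 1:n),
      tumor_size = stats::rlnorm(n, log(4.5), 0.3),
      ajcc_stage = factor(sample(c("2", "3"), n, TRUE), levels = c("2", "3")),
      network_gene_mutated = stats::rbinom(n, 1, 0.4),
      pair_count = stats::rbinom(n, 5, 0.2),
      response = stats::rbinom(n, 1, 0.3))
    ft$cooccurrence_category <- cut(ft$pair_count, c(-Inf, 0, 2, Inf),
                                    labels = c("0", "1-2", "3 or more"))
    suppressWarnings(fit_response_model(ft, "categorical"))$tjur_r2
  })
  expect_lt(mean(tjurs), 0.05)
})

test_that("model selection prefers low AIC with a Tjur tie-break and flags conflicts", {
  mk <- function(aic, tjur, form = "categorical") {
    structure(list(aic = aic, tjur_r2 = tjur, count_form = form),
              class = "response_fit")
  }
  one <- mk(349, 0.14)
  expect_identical(select_model(list(one))$aic, 349)

  sel <- suppressWarnings(select_model(list(mk(349, 0.14), mk(355, 0.10, "continuous"))))
  expect_equal(sel$aic, 349)
  expect_false(any(attr(sel, "candidate_summary")$aic < sel$aic))

  sel_tie <- select_model(list(mk(350, 0.14), mk(350, 0.10, "continuous")))
  expect_equal(sel_tie$tjur_r2, 0.14)

  expect_warning(select_model(list(mk(349, 0.10), mk(355, 0.14, "continuous"))),
                 "not the Tjur")
})

test_that("classification metrics follow the confusion matrix identities", {
  y <- c(1, 1, 1, 0, 0)
  perfect <- performance_metrics(c(1, 1, 1, 0, 0), response = y)
  expect_equal(unname(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               rep(1, 4))

  allpos <- suppressWarnings(performance_metrics(rep(1, 5), response = y))
  expect_equal(unname(allpos["sensitivity"]), 1)
  expect_equal(unname(allpos["specificity"]), 0)
  expect_true(is.nan(allpos[["npv"]]))

  set.seed(10)
  p <- stats::runif(100, 0.01, 0.99)
  y <- stats::rbinom(100, 1, p)
  lo <- suppressWarnings(performance_metrics(p, threshold = 0, response = y))
  hi <- suppressWarnings(performance_metrics(p, threshold = 1, response = y))
  expect_equal(unname(lo["sensitivity"]), 1)
  expect_equal(unname(lo["specificity"]), 0)
  expect_equal(unname(hi["sensitivity"]), 0)
  expect_equal(unname(hi["specificity"]), 1)

  mid <- performance_metrics(p, threshold = 0.5, response = y)
  expect_equal(unname(mid["sensitivity"]) * sum(y == 1), unname(mid["tp"]))
  expect_equal(unname(mid["specificity"]) * sum(y == 0), unname(mid["tn"]))
})

test_that("the closed-loop pipeline recovers the planted category effect at one seed", {
  sim <- simulate_cohort(simulation_preset("closed-loop", seed = 4))
  f <- suppressMessages(filter_variants(sim$maf))
  m <- build_mutation_matrix(f, sim$clinical$sample_id)
  ints <- pairwise_interactions(m, top_mutated_genes(m), adjust = TRUE)
  co <- ints[ints$label == "co-occurring", ]
  scr <- suppressWarnings(screen_predictors(m, co, sim$clinical$response))
  ft <- suppressMessages(build_features(sim$clinical, m, scr))
  fit <- suppressWarnings(fit_response_model(ft, "categorical"))
  row <- fit$coef_table[fit$coef_table$term == "cooccurrence_3plus", ]
  expect_lt(abs(row$estimate - log(8.47)), 2.5 * row$std_error)
})
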