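#' Logistic complete-response prediction pipeline
#'
#' Bivariate screening of gene and co-occurring-pair indicators against tumor
#' response, construction of the network-gene indicator and co-occurrence
#' count category, logistic model fitting with Wald odds-ratio intervals and a
#' likelihood-ratio test for the count term, Tjur-R2/AIC model selection
#' between the categorical and continuous count forms, and training-set
#' classification metrics.
#'
#' @name response_model
#' @keywords internal
NULL

#' Bivariate screening of genes and co-occurring pairs against response
#'
#' Per-gene Fisher test of mutation status vs response, and per-pair Fisher
#' test of the joint-mutation indicator (both genes of the pair mutated in the
#' sample) vs response. Factors with p below `alpha_screen` are retained.
#'
#' @param matrix Binary `mutation_matrix`.
#' @param interactions Pair table from [pairwise_interactions()] (typically
#'   pre-filtered to the co-occurring pairs); may have zero rows.
#' @param response Group labels aligned with the matrix samples.
#' @param alpha_screen Screening level (default 0.1).
#' @param treated Label counted as response = 1 (default `"CR"`).
#' @param direction `"any"` retains every factor with p < alpha_screen (so
#'   `alpha_screen = 1` retains everything); `"CR"` additionally requires
#'   enrichment in the treated group (OR > 1), the screen used for the
#'   response model.
#' @return A `screening_result`: data.frames `genes` (gene, odds_ratio, p) and
#'   `pairs` (gene_a, gene_b, odds_ratio, p), plus `alpha_screen`.
#' @export
screen_predictors <- function(matrix, interactions, response,
                              alpha_screen = 0.1, treated = "CR",
                              direction = c("any", "CR")) {
  direction <- match.arg(direction)
  if (length(response) != nrow(matrix)) stop("response must align with matrix samples")
  y <- response == treated
  n1 <- sum(y)
  n0 <- sum(!y)
  test_indicator <- function(ind) {
    fisher_exact_2x2(c(sum(ind & y), sum(ind & !y),
                       n1 - sum(ind & y), n0 - sum(ind & !y)))
  }
  gene_res <- lapply(colnames(matrix), function(g) test_indicator(matrix[, g] == 1))
  genes <- data.frame(
    gene = colnames(matrix),
    odds_ratio = vapply(gene_res, `[[`, 0, "estimate"),
    p = vapply(gene_res, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE
  )
  keep_g <- genes$p < alpha_screen
  if (direction == "CR") keep_g <- keep_g & genes$odds_ratio > 1
  genes <- genes[keep_g, , drop = FALSE]
  rownames(genes) <- NULL

  if (is.null(interactions) || nrow(interactions) == 0) {
    pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                        odds_ratio = numeric(0), p = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    pair_res <- lapply(seq_len(nrow(interactions)), function(i) {
      ind <- matrix[, interactions$gene_a[i]] == 1 &
        matrix[, interactions$gene_b[i]] == 1
      test_indicator(ind)
    })
    pairs <- data.frame(
      gene_a = interactions$gene_a, gene_b = interactions$gene_b,
      odds_ratio = vapply(pair_res, `[[`, 0, "estimate"),
      p = vapply(pair_res, `[[`, 0, "p_value"),
      stringsAsFactors = FALSE
    )
    keep_p <- pairs$p < alpha_screen
    if (direction == "CR") keep_p <- keep_p & pairs$odds_ratio > 1
    pairs <- pairs[keep_p, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  if (nrow(genes) == 0 && nrow(pairs) == 0) {
    warning("no gene or pair passed the screen; downstream model will omit mutation terms")
  }
  structure(list(genes = genes, pairs = pairs, alpha_screen = alpha_screen,
                 treated = treated, direction = direction),
            class = "screening_result")
}

#' Build the response-model feature table
#'
#' Per sample: tumor size (cm), AJCC stage (factor 2/3), the network-gene
#' indicator (1 iff the sample carries a mutation in any screened gene), the
#' screened-pair count (number of screened pairs with both members mutated)
#' and its category (0 / "1-2" / "3 or more"), and the binary response.
#' Rows with missing tumor size or stage are dropped with a message.
#'
#' @param clinical Clinical data.frame (needs `sample_id`, `response`,
#'   `tumor_size`, `ajcc_stage`).
#' @param matrix Binary `mutation_matrix` covering the clinical samples.
#' @param screening A `screening_result` from [screen_predictors()].
#' @param treated Label mapped to response = 1 (default `"CR"`).
#' @return Data.frame with columns `sample_id`, `tumor_size`, `ajcc_stage`,
#'   `network_gene_mutated`, `pair_count`, `cooccurrence_category`,
#'   `response`; attribute `n_dropped`.
#' @export
build_features <- function(clinical, matrix, screening, treated = "CR") {
  stopifnot(inherits(screening, "screening_result"))
  keep <- !is.na(clinical$tumor_size) & !is.na(clinical$ajcc_stage)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("build_features: dropped %d row(s) with missing tumor size or stage", n_dropped))
  }
  cl <- clinical[keep, , drop = FALSE]
  idx <- match(cl$sample_id, rownames(matrix))
  if (anyNA(idx)) stop("clinical sample(s) absent from the mutation matrix")
  sub <- matrix[idx, , drop = FALSE]

  sg <- intersect(screening$genes$gene, colnames(sub))
  net <- if (length(sg)) as.integer(rowSums(sub[, sg, drop = FALSE]) >= 1) else
    rep(0L, nrow(sub))

  if (nrow(screening$pairs)) {
    pc <- rep(0L, nrow(sub))
    for (i in seq_len(nrow(screening$pairs))) {
      pc <- pc + as.integer(sub[, screening$pairs$gene_a[i]] == 1 &
                              sub[, screening$pairs$gene_b[i]] == 1)
    }
  } else {
    pc <- rep(0L, nrow(sub))
  }
  category <- cut(pc, breaks = c(-Inf, 0, 2, Inf),
                  labels = c("0", "1-2", "3 or more"))
  out <- data.frame(
    sample_id = cl$sample_id,
    tumor_size = cl$tumor_size,
    ajcc_stage = factor(as.character(cl$ajcc_stage), levels = c("2", "3")),
    network_gene_mutated = net,
    pair_count = pc,
    cooccurrence_category = category,
    response = as.integer(cl$response == treated),
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

response_design <- function(features, count_form) {
  x <- cbind(`(Intercept)` = 1,
             tumor_size = features$tumor_size,
             `ajcc_stage3` = as.numeric(features$ajcc_stage == "3"))
  count_cols <- character(0)
  if (any(features$network_gene_mutated == 1) &&
      any(features$network_gene_mutated == 0)) {
    x <- cbind(x, network_gene = features$network_gene_mutated)
  } else {
    warning("network-gene indicator is constant; term omitted from the model")
  }
  if (count_form == "categorical") {
    cat12 <- as.numeric(features$cooccurrence_category == "1-2")
    cat3 <- as.numeric(features$cooccurrence_category == "3 or more")
    if (any(cat12 == 1)) {
      x <- cbind(x, `cooccurrence_1-2` = cat12)
      count_cols <- c(count_cols, "cooccurrence_1-2")
    } else warning("no samples in co-occurrence category 1-2; dummy omitted")
    if (any(cat3 == 1)) {
      x <- cbind(x, `cooccurrence_3plus` = cat3)
      count_cols <- c(count_cols, "cooccurrence_3plus")
    } else warning("no samples in co-occurrence category 3 or more; dummy omitted")
  } else {
    if (stats::var(features$pair_count) > 0) {
      x <- cbind(x, cooccurrence_count = features$pair_count)
      count_cols <- "cooccurrence_count"
    } else warning("pair count is constant; count term omitted")
  }
  list(x = x, count_cols = count_cols)
}

#' Fit the logistic complete-response model
#'
#' Logistic regression of response on tumor size, AJCC stage (reference 2),
#' the network-gene indicator (reference "no mutation"), and the
#' co-occurrence count as either the 0 / 1-2 / 3-or-more categorical
#' (reference "0") or a continuous count. Reports exponentiated coefficients
#' with Wald 95% intervals, Tjur R-squared, a likelihood-ratio test for the
#' count term via a nested refit, and training-set classification metrics.
#'
#' @param features Feature table from [build_features()].
#' @param count_form `"categorical"` (default) or `"continuous"` functional
#'   form of the co-occurrence count.
#' @param threshold Classification threshold on the fitted probability
#'   (default 0.5).
#' @param conf_level Wald interval level (default 0.95).
#' @return A `response_fit`: the underlying `logistic_fit`, a coefficient
#'   table with odds ratios and intervals, `tjur_r2`, `aic`, `lrt`
#'   (statistic, df, p for the count term), `metrics`, and `count_form`.
#' @export
fit_response_model <- function(features, count_form = c("categorical", "continuous"),
                               threshold = 0.5, conf_level = 0.95) {
  count_form <- match.arg(count_form)
  if (nrow(features) < 20) stop("need at least 20 observations")
  if (length(unique(features$response)) < 2) stop("both response classes must be present")
  des <- response_design(features, count_form)
  fit <- logistic_mle(des$x, features$response)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- fit$coefficients
  se <- fit$standard_errors
  coef_table <- data.frame(
    term = names(beta),
    estimate = as.numeric(beta),
    std_error = as.numeric(se),
    odds_ratio = exp(as.numeric(beta)),
    ci_low = exp(as.numeric(beta) - z * as.numeric(se)),
    ci_high = exp(as.numeric(beta) + z * as.numeric(se)),
    p_value = 2 * stats::pnorm(-abs(as.numeric(beta) / as.numeric(se))),
    stringsAsFactors = FALSE
  )

  lrt <- NULL
  if (length(des$count_cols)) {
    reduced_x <- des$x[, setdiff(colnames(des$x), des$count_cols), drop = FALSE]
    reduced <- logistic_mle(reduced_x, features$response)
    stat <- 2 * (fit$log_likelihood - reduced$log_likelihood)
    lrt <- list(statistic = stat, df = length(des$count_cols),
                p_value = stats::pchisq(stat, df = length(des$count_cols),
                                        lower.tail = FALSE))
  }

  out <- structure(
    list(fit = fit, coef_table = coef_table,
         tjur_r2 = tjur_r2(fit, features$response),
         aic = fit$aic, n_obs = fit$n_obs, lrt = lrt,
         count_form = count_form, threshold = threshold,
         response = features$response),
    class = "response_fit"
  )
  out$metrics <- performance_metrics(out, threshold)
  out
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf("Complete-response model (%s count form): %d obs, AIC = %.2f, Tjur R2 = %.3f\n",
              x$count_form, x$n_obs, x$aic, x$tjur_r2))
  tab <- x$coef_table
  tab$odds_ratio <- round(tab$odds_ratio, 2)
  tab$ci_low <- round(tab$ci_low, 2)
  tab$ci_high <- round(tab$ci_high, 2)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab[, c("term", "odds_ratio", "ci_low", "ci_high", "p_value")],
        row.names = FALSE)
  if (!is.null(x$lrt)) {
    cat(sprintf("Likelihood-ratio test for the co-occurrence term: chi2 = %.3f (df %d), p = %.4g\n",
                x$lrt$statistic, x$lrt$df, x$lrt$p_value))
  }
  cat(sprintf("Training metrics @ %.2f: sens %.3f, spec %.3f, PPV %.3f, NPV %.3f\n",
              x$threshold, x$metrics["sensitivity"], x$metrics["specificity"],
              x$metrics["ppv"], x$metrics["npv"]))
  invisible(x)
}

#' Select the final model by AIC with a Tjur-R2 tie-break
#'
#' Lowest AIC wins; a tie (difference below 1e-6) is broken by the highest
#' Tjur R-squared. When the AIC winner is not also the Tjur winner, the AIC
#' winner is returned with an explicit conflict warning.
#'
#' @param candidates List of `response_fit` objects (at least one).
#' @return The selected `response_fit`, with attribute `candidate_summary`
#'   reporting AIC and Tjur R-squared for every candidate.
#' @export
select_model <- function(candidates) {
  if (length(candidates) < 1) stop("need at least one candidate model")
  aics <- vapply(candidates, `[[`, 0, "aic")
  tjurs <- vapply(candidates, `[[`, 0, "tjur_r2")
  best_aic <- which(aics <= min(aics) + 1e-6)
  pick <- best_aic[which.max(tjurs[best_aic])]
  if (tjurs[pick] < max(tjurs) - 1e-12) {
    warning(sprintf(
      "AIC-best model (#%d) is not the Tjur-R2-best model (#%d); AIC winner chosen",
      pick, which.max(tjurs)))
  }
  summary <- data.frame(
    candidate = seq_along(candidates),
    count_form = vapply(candidates, `[[`, "", "count_form"),
    aic = aics, tjur_r2 = tjurs, selected = seq_along(candidates) == pick,
    stringsAsFactors = FALSE
  )
  out <- candidates[[pick]]
  attr(out, "candidate_summary") <- summary
  out
}

#' Training-set classification metrics
#'
#' Classifies fitted probability >= `threshold` as a predicted complete
#' response and computes sensitivity, specificity, PPV, and NPV from the
#' training confusion matrix. Ratios with zero denominators are returned as
#' `NaN` with a warning.
#'
#' @param fit A `response_fit` (or `logistic_fit` plus `response`).
#' @param threshold Probability threshold (default 0.5).
#' @param response Binary response; taken from `fit` when omitted.
#' @return Named vector: sensitivity, specificity, ppv, npv, plus the
#'   confusion counts tp/fp/tn/fn.
#' @export
performance_metrics <- function(fit, threshold = 0.5, response = NULL) {
  if (inherits(fit, "response_fit")) {
    p <- fit$fit$fitted_probabilities
    if (is.null(response)) response <- fit$response
  } else if (inherits(fit, "logistic_fit")) {
    p <- fit$fitted_probabilities
  } else {
    p <- as.numeric(fit)
  }
  if (is.null(response)) stop("response is required")
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & response == 1)
  fp <- sum(pred == 1 & response == 0)
  tn <- sum(pred == 0 & response == 0)
  fn <- sum(pred == 0 & response == 1)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  c(sensitivity = safe_div(tp, tp + fn, "sensitivity"),
    specificity = safe_div(tn, tn + fp, "specificity"),
    ppv = safe_div(tp, tp + fp, "PPV"),
    npv = safe_div(tn, tn + fn, "NPV"),
    tp = tp, fp = fp, tn = tn, fn = fn)
}
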