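#' Matching-weight propensity-score balancing of CR vs ICR cohorts
#'
#' Fits a logistic propensity model for complete response, converts the scores
#' to matching weights (the weighting analogue of 1:1 matching), checks
#' per-covariate standardized differences against the 10% convention, and
#' iteratively augments the propensity model (squared terms, then pairwise
#' interactions) until all covariates balance or the iteration cap is hit.
#' The balanced weights then feed the weighted t-test contrast of tumor
#' mutation burden.
#'
#' @name balance
#' @keywords internal
NULL

#' Default balancing covariates
#' @return The clinical fields balanced by default: age, gender, BMI, tumor
#'   size, T stage, N stage.
#' @export
default_balance_covariates <- function() {
  c("age", "gender", "bmi", "tumor_size", "t_stage", "n_stage")
}

#' Propensity model specification
#'
#' @param covariates Clinical field names entering the propensity model.
#' @param model_terms Term labels: main effects (covariate names), squared
#'   terms (`"age^2"`), or pairwise interactions (`"age:bmi"`). Defaults to
#'   the main effects.
#' @param treated Group treated as "exposed" in the matching-weight formula
#'   (default `"CR"`).
#' @return A `propensity_spec`.
#' @export
propensity_spec <- function(covariates = default_balance_covariates(),
                            model_terms = covariates, treated = "CR") {
  if (length(covariates) == 0) stop("covariate list must be non-empty")
  structure(list(covariates = covariates, model_terms = model_terms,
                 treated = treated),
            class = "propensity_spec")
}

# Numeric encoding of clinical covariates: numerics pass through, two-level
# factors become 0/1 (second sorted level = 1), multi-level labels become
# integer ranks of the sorted levels (ordinal stage labels T2 < T3 < T4 etc).
encode_covariates <- function(clinical, covariates) {
  missing_cov <- setdiff(covariates, names(clinical))
  if (length(missing_cov)) {
    stop("clinical table lacks covariate(s): ", paste(missing_cov, collapse = ", "))
  }
  mat <- matrix(NA_real_, nrow = nrow(clinical), ncol = length(covariates),
                dimnames = list(clinical$sample_id, covariates))
  is_binary <- logical(length(covariates))
  for (j in seq_along(covariates)) {
    v <- clinical[[covariates[j]]]
    if (is.numeric(v)) {
      mat[, j] <- v
      is_binary[j] <- all(stats::na.omit(v) %in% c(0, 1))
    } else {
      lev <- sort(unique(stats::na.omit(as.character(v))))
      if (length(lev) < 2) {
        mat[, j] <- as.numeric(!is.na(v))  # constant column; flagged by the fit
        is_binary[j] <- TRUE
      } else if (length(lev) == 2) {
        mat[, j] <- as.numeric(as.character(v) == lev[2])
        is_binary[j] <- TRUE
      } else {
        mat[, j] <- as.numeric(match(as.character(v), lev))
        is_binary[j] <- FALSE
      }
    }
  }
  list(mat = mat, is_binary = stats::setNames(is_binary, covariates))
}

# Design matrix for a term list over standardized covariates.
build_term_design <- function(zmat, terms) {
  cols <- lapply(terms, function(tm) {
    if (grepl("\\^2$", tm)) {
      v <- sub("\\^2$", "", tm)
      zmat[, v]^2
    } else if (grepl(":", tm, fixed = TRUE)) {
      parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
      zmat[, parts[1]] * zmat[, parts[2]]
    } else {
      zmat[, tm]
    }
  })
  x <- do.call(cbind, cols)
  colnames(x) <- terms
  cbind(`(Intercept)` = 1, x)
}

#' Fit the propensity model for complete response
#'
#' Logistic regression of treated-group membership on the specified terms.
#' Continuous covariates are standardized internally before fitting; rows with
#' any missing covariate are excluded (complete-case) with a message. Scores
#' are clipped to \[1e-6, 1 - 1e-6\].
#'
#' @param clinical Clinical data.frame (one row per patient).
#' @param spec A [propensity_spec()].
#' @return List with `scores` (clipped fitted probabilities for the kept
#'   rows), `kept` (row indices used), `fit` (the `logistic_fit`), and the
#'   encoded covariate matrix.
#' @export
fit_propensity <- function(clinical, spec = propensity_spec()) {
  stopifnot(inherits(spec, "propensity_spec"))
  enc <- encode_covariates(clinical, spec$covariates)
  kept <- which(stats::complete.cases(enc$mat))
  n_drop <- nrow(clinical) - length(kept)
  if (n_drop > 0) {
    message(sprintf("fit_propensity: excluded %d row(s) with missing covariates", n_drop))
  }
  mat <- enc$mat[kept, , drop = FALSE]
  zmat <- mat
  for (j in seq_len(ncol(zmat))) {
    if (!enc$is_binary[j]) {
      s <- stats::sd(zmat[, j])
      zmat[, j] <- (zmat[, j] - mean(zmat[, j])) / if (s > 0) s else 1
    }
  }
  x <- build_term_design(zmat, spec$model_terms)
  sds <- apply(x[, -1, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    message("fit_propensity: dropping constant term(s): ",
            paste(colnames(x)[-1][sds == 0], collapse = ", "))
    x <- x[, c(TRUE, sds > 0), drop = FALSE]
  }
  y <- as.numeric(clinical$response[kept] == spec$treated)
  fit <- tryCatch(
    logistic_mle(x, y),
    error = function(e) {
      stop("propensity model failed (", conditionMessage(e),
           "); consider simplifying the model terms", call. = FALSE)
    }
  )
  if (fit$separated) {
    warning("propensity model shows separation; consider simplifying the model terms")
  }
  scores <- pmin(pmax(fit$fitted_probabilities, 1e-6), 1 - 1e-6)
  list(scores = scores, kept = kept, fit = fit,
       covariate_matrix = mat, is_binary = enc$is_binary, zmat = zmat)
}

#' Matching weights from propensity scores
#'
#' For the treated group `w = min(e, 1-e)/e`; for the comparison group
#' `w = min(e, 1-e)/(1-e)`, where `e` is the treated-group propensity. Weights
#' lie in (0, 1\] and equal 1 exactly at `e = 0.5` or on a sample's
#' minority-probability side.
#'
#' @param scores Propensity scores strictly inside (0, 1).
#' @param group Group labels aligned with `scores`.
#' @param treated Label of the treated group (default `"CR"`).
#' @return Numeric weights in (0, 1\].
#' @export
matching_weights <- function(scores, group, treated = "CR") {
  if (any(scores <= 0 | scores >= 1)) {
    stop("propensity scores must lie strictly inside (0, 1); clip upstream")
  }
  if (length(scores) != length(group)) stop("scores and group must align")
  ifelse(group == treated,
         pmin(scores, 1 - scores) / scores,
         pmin(scores, 1 - scores) / (1 - scores))
}

#' Per-covariate balance diagnostics
#'
#' Standardized differences (percent) before (unit weights) and after the
#' supplied weighting, per covariate.
#'
#' @param clinical Clinical data.frame.
#' @param weights Per-row weights aligned with `clinical` rows.
#' @param spec A [propensity_spec()].
#' @param threshold Balance threshold in percent (default 10).
#' @return A `balance_report` data.frame (covariate, before, after) with
#'   attribute `converged` = all after-values strictly below `threshold`.
#' @export
balance_report <- function(clinical, weights, spec = propensity_spec(),
                           threshold = 10) {
  if (length(weights) != nrow(clinical)) stop("weights must align with clinical rows")
  enc <- encode_covariates(clinical, spec$covariates)
  t_idx <- clinical$response == spec$treated
  before <- after <- numeric(length(spec$covariates))
  for (j in seq_along(spec$covariates)) {
    v <- enc$mat[, j]
    b <- enc$is_binary[j]
    before[j] <- standardized_difference(v[t_idx], v[!t_idx], binary = b)
    after[j] <- standardized_difference(v[t_idx], v[!t_idx],
                                        weights[t_idx], weights[!t_idx],
                                        binary = b)
  }
  rep <- data.frame(covariate = spec$covariates, before = before, after = after,
                    stringsAsFactors = FALSE)
  attr(rep, "converged") <- all(is.finite(after)) && all(after < threshold)
  attr(rep, "threshold") <- threshold
  class(rep) <- c("balance_report", class(rep))
  rep
}

# Next augmentation term given the current terms and the worst-balanced
# continuous covariates (by after-weighting standardized difference).
next_augmentation <- function(terms, report, is_binary) {
  cont <- report$covariate[!is_binary[report$covariate]]
  if (length(cont) == 0) return(NULL)
  ord <- cont[order(-report$after[match(cont, report$covariate)])]
  worst <- ord[1]
  sq <- paste0(worst, "^2")
  if (!sq %in% terms) return(sq)
  for (other in ord[-1]) {
    inter <- paste0(worst, ":", other)
    inter_rev <- paste0(other, ":", worst)
    if (!inter %in% terms && !inter_rev %in% terms) return(inter)
  }
  # worst covariate exhausted; fall through to squares of the next offenders
  for (other in ord[-1]) {
    sq <- paste0(other, "^2")
    if (!sq %in% terms) return(sq)
  }
  NULL
}

#' Iterative matching-weight balancing
#'
#' Repeats propensity fit, matching weights, and balance check until every
#' covariate's weighted standardized difference falls below `threshold`
#' percent. When a check fails, the model is augmented with the squared term
#' of the worst-balanced continuous covariate (or, once its square is present,
#' its interaction with the next-worst), and refit. Stops on convergence or
#' after `max_iter` iterations (with a warning, never silent success).
#'
#' @param clinical Clinical data.frame.
#' @param spec A [propensity_spec()].
#' @param threshold Balance criterion in percent (default 10).
#' @param max_iter Iteration cap (default 10).
#' @return A `balanced_cohort`: sample ids, propensity scores, matching
#'   weights, group labels, final `balance_report`, per-iteration history,
#'   `iterations_used`, `converged`, `final_terms`, and the count of
#'   complete-case-excluded rows.
#' @export
iterate_balance <- function(clinical, spec = propensity_spec(),
                            threshold = 10, max_iter = 10L) {
  stopifnot(inherits(spec, "propensity_spec"), max_iter >= 1)
  terms <- spec$model_terms
  history <- list()
  pf <- NULL
  rep <- NULL
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    cur_spec <- propensity_spec(spec$covariates, terms, spec$treated)
    pf <- fit_propensity(clinical, cur_spec)
    sub <- clinical[pf$kept, , drop = FALSE]
    w <- matching_weights(pf$scores, sub$response, spec$treated)
    rep <- balance_report(sub, w, cur_spec, threshold)
    history[[it]] <- list(terms = terms, report = rep,
                          converged = attr(rep, "converged"))
    if (attr(rep, "converged")) {
      converged <- TRUE
      break
    }
    aug <- next_augmentation(terms, rep, pf$is_binary)
    if (is.null(aug)) break
    terms <- c(terms, aug)
  }
  if (!converged) {
    warning(sprintf(
      "balance iteration did not reach all standardized differences < %g%% after %d iteration(s)",
      threshold, iterations))
  }
  sub <- clinical[pf$kept, , drop = FALSE]
  structure(
    list(sample_ids = sub$sample_id,
         propensity_scores = pf$scores,
         matching_weights = matching_weights(pf$scores, sub$response, spec$treated),
         group = sub$response,
         report = rep,
         history = history,
         iterations_used = iterations,
         converged = converged,
         final_terms = terms,
         n_excluded = nrow(clinical) - length(pf$kept),
         treated = spec$treated),
    class = "balanced_cohort"
  )
}

#' @export
print.balanced_cohort <- function(x, ...) {
  cat(sprintf("Balanced cohort: %d samples (%d %s / %d other), %d excluded\n",
              length(x$sample_ids), sum(x$group == x$treated), x$treated,
              sum(x$group != x$treated), x$n_excluded))
  cat(sprintf("  %s after %d iteration(s); terms: %s\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations_used, paste(x$final_terms, collapse = ", ")))
  print(transform(x$report, before = round(before, 2), after = round(after, 2)))
  invisible(x)
}

#' Weighted comparison of tumor mutation burden between CR and ICR
#'
#' Runs the weighted Welch t-test on per-sample mutation rates using the
#' matching weights; the estimate is the weighted mean difference
#' (treated minus comparison, i.e. CR - ICR by default).
#'
#' @param tmb Per-sample mutation rates (mutations/Mb).
#' @param group Aligned group labels.
#' @param weights Aligned weights (e.g. matching weights).
#' @param treated Treated-group label (default `"CR"`).
#' @return A `cr_test_result`.
#' @export
compare_tmb_weighted <- function(tmb, group, weights, treated = "CR") {
  if (length(tmb) != length(group) || length(tmb) != length(weights)) {
    stop("tmb, group and weights must align")
  }
  t_idx <- group == treated
  weighted_ttest(tmb[t_idx], tmb[!t_idx], weights[t_idx], weights[!t_idx])
}
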