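#' Statistical primitives for the CR/ICR cohort analysis
#'
#' Exact and asymptotic 2x2 tests, Benjamini-Hochberg adjustment, a weighted
#' Welch t-test with reliability weights, maximum-likelihood logistic
#' regression via IRLS, Tjur's discrimination coefficient, and weighted
#' standardized differences. Every downstream stage (balancing, mutation
#' networks, response modelling) builds on these.
#'
#' @name statcore
#' @keywords internal
NULL

new_test_result <- function(statistic, p_value, estimate, df = NA_real_, method) {
  stopifnot(is.character(method), length(method) == 1L, nzchar(method))
  p_value <- as.numeric(p_value)
  if (!is.na(p_value)) p_value <- min(max(p_value, 0), 1)
  structure(
    list(statistic = as.numeric(statistic), p_value = p_value,
         estimate = as.numeric(estimate), df = as.numeric(df), method = method),
    class = "cr_test_result"
  )
}

#' @export
print.cr_test_result <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  cat(sprintf("  statistic = %.6g, estimate = %.6g, df = %s, p = %.6g\n",
              x$statistic, x$estimate,
              if (is.na(x$df)) "NA" else format(x$df, digits = 5), x$p_value))
  invisible(x)
}

#' Validate and coerce a 2x2 contingency table
#'
#' Accepts a 2x2 matrix or a length-4 vector `c(a, b, c, d)` laid out row-wise
#' (rows = factor 1 present/absent, columns = factor 2 present/absent).
#'
#' @param tab 2x2 matrix or length-4 numeric vector of non-negative integer counts.
#' @return A 2x2 numeric matrix.
#' @export
as_table2x2 <- function(tab) {
  if (is.numeric(tab) && length(tab) == 4L && is.null(dim(tab))) {
    tab <- matrix(tab, nrow = 2L, ncol = 2L, byrow = TRUE)
  }
  tab <- as.matrix(tab)
  if (!is.numeric(tab) || any(dim(tab) != 2L)) {
    stop("a 2x2 table requires four counts (a, b, c, d) or a 2x2 matrix")
  }
  if (any(!is.finite(tab)) || any(tab < 0) || any(abs(tab - round(tab)) > 1e-8)) {
    stop("2x2 table cells must be finite non-negative integers")
  }
  storage.mode(tab) <- "double"
  round(tab)
}

haldane_or <- function(tab) {
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities (margins fixed)
#' of every table whose probability is at most that of the observed table, with
#' a relative tolerance of 1e-7 to guard floating-point ties. The reported
#' estimate is the sample odds ratio ad/bc; when any cell is zero, 0.5 is added
#' to every cell for the estimate only (Haldane correction), never for the
#' p-value.
#'
#' @param tab 2x2 table as accepted by [as_table2x2()].
#' @return A `cr_test_result` with the p-value, odds-ratio estimate, and the
#'   observed table probability as `statistic`.
#' @examples
#' fisher_exact_2x2(c(3, 1, 1, 3))  # p = 34/70
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as_table2x2(tab)
  n <- sum(tab)
  if (n < 1) stop("degenerate 2x2 table: all cells are zero")
  a <- tab[1, 1]
  r1 <- tab[1, 1] + tab[1, 2]
  c1 <- tab[1, 1] + tab[2, 1]
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  new_test_result(statistic = p_obs, p_value = p, estimate = haldane_or(tab),
                  method = "Fisher's exact test (two-sided, 2x2)")
}

#' Pearson chi-squared test with Yates continuity correction
#'
#' Chi-squared statistic on a 2x2 table with |O - E| reduced by 0.5 (floored at
#' zero) in each cell, df = 1, upper-tail p-value. All expected counts must be
#' positive, i.e. no zero row or column margin.
#'
#' @inheritParams fisher_exact_2x2
#' @return A `cr_test_result`; the estimate is the (Haldane-corrected) odds ratio.
#' @export
chi2_yates <- function(tab) {
  tab <- as_table2x2(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate 2x2 table: zero row or column margin")
  }
  expected <- outer(rs, cs) / sum(tab)
  stat <- sum(pmax(abs(tab - expected) - 0.5, 0)^2 / expected)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  new_test_result(statistic = stat, p_value = p, estimate = haldane_or(tab),
                  df = 1, method = "Pearson chi-squared with Yates continuity correction")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the original order, each in \[0, 1\].
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

weighted_moments <- function(x, w) {
  if (length(x) != length(w)) stop("values and weights must have equal length")
  if (anyNA(x) || anyNA(w) || any(!is.finite(w))) stop("values/weights must be finite")
  if (any(w < 0)) stop("weights must be non-negative")
  sw <- sum(w)
  sw2 <- sum(w^2)
  if (sw <= 0) stop("zero total weight")
  if (sum(w > 0) < 2L) stop("at least 2 entries with positive weight are required")
  m <- sum(w * x) / sw
  # reliability-weight variance with effective sample size (sum w)^2 / sum w^2
  v <- sum(w * (x - m)^2) * sw / (sw^2 - sw2)
  list(mean = m, var = v, n_eff = sw^2 / sw2)
}

#' Weighted two-sample Welch t-test
#'
#' Weighted means and reliability-weight variances with effective sample sizes
#' \eqn{n_{eff} = (\sum w)^2 / \sum w^2}; Welch-Satterthwaite degrees of
#' freedom computed on the effective sizes; two-sided p-value. With unit
#' weights this reduces exactly to the unweighted Welch t-test.
#'
#' @param values1,values0 Numeric vectors for the two groups (group 1 minus
#'   group 0 in the estimate).
#' @param weights1,weights0 Non-negative weights, defaulting to unit weights.
#' @return A `cr_test_result` with `estimate` = weighted mean difference.
#' @export
weighted_ttest <- function(values1, values0,
                           weights1 = rep(1, length(values1)),
                           weights0 = rep(1, length(values0))) {
  g1 <- weighted_moments(values1, weights1)
  g0 <- weighted_moments(values0, weights0)
  if (g1$n_eff <= 1 || g0$n_eff <= 1) stop("each group needs effective sample size > 1")
  diff <- g1$mean - g0$mean
  se2 <- g1$var / g1$n_eff + g0$var / g0$n_eff
  if (se2 == 0) {
    # zero variance in both groups: equal means give p = 1 by convention
    t_stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
    df <- NA_real_
  } else {
    t_stat <- diff / sqrt(se2)
    df <- se2^2 / ((g1$var / g1$n_eff)^2 / (g1$n_eff - 1) +
                     (g0$var / g0$n_eff)^2 / (g0$n_eff - 1))
    p <- 2 * stats::pt(-abs(t_stat), df = df)
  }
  new_test_result(statistic = t_stat, p_value = p, estimate = diff, df = df,
                  method = "Weighted Welch two-sample t-test (reliability weights)")
}

#' Weighted standardized difference between two groups, in percent
#'
#' \eqn{100 |\bar x_1 - \bar x_0| / \sqrt{(s_1^2 + s_0^2)/2}} using the same
#' weighted mean/variance conventions as [weighted_ttest()]. For binary
#' covariates the group variance is \eqn{p(1-p)}. Invariant to rescaling all
#' weights by a constant.
#'
#' @inheritParams weighted_ttest
#' @param binary If `NULL` (default), a covariate whose values all lie in
#'   \{0, 1\} is treated as binary; set `TRUE`/`FALSE` to force.
#' @return Percent standardized difference; 0 when both variances are zero and
#'   the means agree, `Inf` when both variances are zero but the means differ.
#' @export
standardized_difference <- function(values1, values0,
                                    weights1 = rep(1, length(values1)),
                                    weights0 = rep(1, length(values0)),
                                    binary = NULL) {
  g1 <- weighted_moments(values1, weights1)
  g0 <- weighted_moments(values0, weights0)
  if (is.null(binary)) {
    binary <- all(c(values1, values0) %in% c(0, 1))
  }
  if (binary) {
    v1 <- g1$mean * (1 - g1$mean)
    v0 <- g0$mean * (1 - g0$mean)
  } else {
    v1 <- g1$var
    v0 <- g0$var
  }
  denom <- sqrt((v1 + v0) / 2)
  num <- abs(g1$mean - g0$mean)
  if (denom == 0) {
    return(if (num == 0) 0 else Inf)
  }
  100 * num / denom
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Fits the Bernoulli MLE by iteratively reweighted least squares. Convergence
#' is declared when the maximum absolute score drops below `tol_score` or the
#' maximum coefficient change drops below `tol_coef`. Standard errors come from
#' the inverse observed information. Perfect separation is flagged (not
#' silenced) when any coefficient exceeds 15 on its standardized scale.
#'
#' @param x Design matrix including the intercept column.
#' @param y Binary response vector (0/1).
#' @param weights Optional non-negative prior weights.
#' @param max_iter,tol_score,tol_coef IRLS controls.
#' @return An object of class `logistic_fit`: coefficients (intercept first),
#'   standard errors, log-likelihood, AIC, n_obs, convergence/separation flags,
#'   and fitted probabilities.
#' @export
logistic_mle <- function(x, y, weights = NULL, max_iter = 100L,
                         tol_score = 1e-8, tol_coef = 1e-10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- nrow(x)
  k <- ncol(x)
  if (length(y) != n) stop("response length must match the design matrix")
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (n < k) stop("need at least as many observations as coefficients")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || anyNA(weights)) {
    stop("weights must be non-negative and aligned with the observations")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(k))

  dec <- qr(x * sqrt(pmax(weights, .Machine$double.eps)))
  if (dec$rank < k) {
    bad <- colnames(x)[dec$pivot[seq.int(dec$rank + 1L, k)]]
    stop("rank-deficient design matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  beta <- numeric(k)
  converged <- FALSE
  info <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    p <- stats::plogis(eta)
    wirls <- weights * p * (1 - p)
    score <- drop(crossprod(x, weights * (y - p)))
    info <- crossprod(x, x * pmax(wirls, 1e-12))
    delta <- tryCatch(solve(info, score), error = function(e) {
      stop("information matrix is singular during IRLS (quasi-separation?)")
    })
    beta <- beta + delta
    if (max(abs(score)) < tol_score || max(abs(delta)) < tol_coef) {
      converged <- TRUE
      break
    }
  }

  eta <- pmin(pmax(drop(x %*% beta), -30), 30)
  p <- stats::plogis(eta)
  info <- crossprod(x, x * pmax(weights * p * (1 - p), 1e-12))
  se <- sqrt(diag(solve(info)))
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(weights * (y * log(pc) + (1 - y) * log(1 - pc)))
  aic <- 2 * k - 2 * ll

  # separation heuristic: coefficient magnitude on standardized columns
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1  # intercept / constant columns judged on raw scale
  separated <- any(abs(beta * sds) > 15)
  if (separated) {
    converged <- FALSE
    warning("possible (quasi-)separation: a standardized coefficient exceeds 15; ",
            "estimates and standard errors are unreliable")
  }

  structure(
    list(coefficients = stats::setNames(beta, colnames(x)),
         standard_errors = stats::setNames(se, colnames(x)),
         log_likelihood = ll, aic = aic, n_obs = n,
         converged = converged, separated = separated,
         fitted_probabilities = p, iterations = iter),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: %d obs, %d coefficients, logLik = %.4f, AIC = %.4f%s\n",
              x$n_obs, length(x$coefficients), x$log_likelihood, x$aic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(rbind(coef = x$coefficients, se = x$standard_errors), 5))
  invisible(x)
}

#' Tjur's coefficient of discrimination
#'
#' Mean fitted probability among responders minus mean among non-responders;
#' lies in \[-1, 1\].
#'
#' @param fit A `logistic_fit`, or a numeric vector of fitted probabilities.
#' @param response Binary response aligned with the fitted probabilities.
#' @return Tjur R-squared.
#' @export
tjur_r2 <- function(fit, response) {
  p <- if (inherits(fit, "logistic_fit")) fit$fitted_probabilities else as.numeric(fit)
  response <- as.numeric(response)
  if (length(p) != length(response)) stop("fitted probabilities and response must align")
  if (!all(response %in% c(0, 1))) stop("response must be binary 0/1")
  if (all(response == 1) || all(response == 0)) {
    stop("Tjur R-squared is undefined when the response has a single class")
  }
  mean(p[response == 1]) - mean(p[response == 0])
}
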