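# Case/control predictive metrics: Nagelkerke R2 via a self-contained
# logistic fit, rank-based AUC, the Yates-corrected two-proportion test, and
# cross-file score correlation.

coerce_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) {
    dtc_error("dtcprs_bad_input", "labels must be binary (0/1, logical, or 2-level factor)")
  }
  as.integer(labels)
}

# Intercept + slope logistic regression by iteratively reweighted least
# squares. Self-contained so the metric stack has no model-fitting
# dependency in its contract.
logistic_irls <- function(x, y, tol = 1e-10, max_iter = 100L) {
  X <- cbind(1, x)
  beta <- c(stats::qlogis(mean(y) * 0.998 + 0.001), 0)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  ll <- loglik(beta)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    ll_new <- loglik(beta_new)
    converged <- abs(ll_new - ll) < tol
    beta <- beta_new
    ll <- ll_new
    if (converged) break
  }
  list(coef = beta, loglik = ll)
}

#' Nagelkerke's R-squared for a score against a binary outcome
#'
#' Fits intercept-only and intercept-plus-score logistic models by maximum
#' likelihood (iteratively reweighted least squares, convergence when the
#' log-likelihood changes by less than 1e-10, at most 100 iterations), forms
#' the Cox-Snell `R2 = 1 - exp(-(2/n)(l1 - l0))`, and rescales it by its
#' maximum `1 - exp((2/n) l0)` so a perfectly separating score approaches 1.
#'
#' @param scores Numeric score per individual.
#' @param labels Binary outcome (0/1, logical, or 2-level factor).
#' @return Nagelkerke's R-squared in `[0, 1]`. Signals
#'   `dtcprs_degenerate_input` when a class is absent, and a
#'   `dtcprs_separation` warning when the fitted slope indicates complete
#'   separation (|coefficient| > 50).
#' @export
nagelkerke_r2 <- function(scores, labels) {
  y <- coerce_labels(labels)
  if (length(scores) != length(y)) {
    dtc_error("dtcprs_bad_input", "scores and labels must have equal length")
  }
  if (sum(y) == 0L || sum(y) == length(y)) {
    dtc_error("dtcprs_degenerate_input", "both classes must be present")
  }
  n <- length(y)
  p0 <- mean(y)
  ll0 <- sum(y) * log(p0) + sum(1 - y) * log(1 - p0)
  if (stats::var(scores) == 0) {
    return(0)
  }
  fit <- logistic_irls(scores, y)
  if (abs(fit$coef[2]) > 50 || fit$loglik > -1e-6) {
    dtc_warn("dtcprs_separation",
             "scores (quasi-)completely separate the classes; R2 sits at the Nagelkerke bound")
  }
  ll1 <- max(fit$loglik, ll0)
  r2_cs <- 1 - exp(-(2 / n) * (ll1 - ll0))
  r2_cs / (1 - exp((2 / n) * ll0))
}

#' Area under the ROC curve (concordance probability)
#'
#' Mann-Whitney form computed by midranks: the probability that a random
#' case scores above a random control, with ties counted as one half.
#'
#' @param scores Numeric score per individual.
#' @param labels Binary outcome.
#' @return AUC in `[0, 1]`. Signals `dtcprs_degenerate_input` when a class
#'   is absent.
#' @export
auc <- function(scores, labels) {
  y <- coerce_labels(labels)
  if (length(scores) != length(y)) {
    dtc_error("dtcprs_bad_input", "scores and labels must have equal length")
  }
  n1 <- sum(y)
  n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L) {
    dtc_error("dtcprs_degenerate_input", "both classes must be present")
  }
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-proportion test with continuity correction
#'
#' Pooled two-proportion z-test with the Yates continuity correction: the
#' absolute difference in sample proportions is reduced by
#' `(1/n1 + 1/n2)/2` (floored at zero) before standardizing by the pooled
#' standard error; the p-value is two-sided normal. Degenerate pooled
#' proportions (0 or 1) return p = 1.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return An object of class `htest` with the z statistic, two-sided
#'   p-value and the two sample proportions.
#' @export
#' @examples
#' two_proportion_test(20, 25, 33, 39)$p.value  # ~0.89, prints as 0.9
two_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 < 1L || n2 < 1L || k1 < 0L || k2 < 0L || k1 > n1 || k2 > n2) {
    dtc_error("dtcprs_bad_input", "need 0 <= k <= n and n >= 1 in both groups")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    z <- 0
    p <- 1
  } else {
    se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
    cc <- (1 / n1 + 1 / n2) / 2
    z <- max(0, abs(p1 - p2) - cc) / se
    p <- min(1, 2 * stats::pnorm(-z))
  }
  structure(
    list(statistic = c(z = z),
         p.value = p,
         estimate = c(proportion1 = p1, proportion2 = p2),
         method = "Two-sample test of proportions with continuity correction",
         data.name = sprintf("%d/%d vs %d/%d", k1, n1, k2, n2)),
    class = "htest"
  )
}

#' Pearson correlation of per-trait scores between two runs
#'
#' Reproducibility statistic for the same person processed through two
#' different data files: the correlation of the paired per-trait scores.
#'
#' @param results_a,results_b Numeric score vectors; when named, they are
#'   paired by shared names, otherwise by position.
#' @return Pearson r over the shared traits. Signals
#'   `dtcprs_degenerate_input` with fewer than 3 shared traits or zero
#'   variance in either vector.
#' @export
score_correlation <- function(results_a, results_b) {
  if (!is.null(names(results_a)) && !is.null(names(results_b))) {
    shared <- intersect(names(results_a), names(results_b))
    a <- results_a[shared]
    b <- results_b[shared]
  } else {
    if (length(results_a) != length(results_b)) {
      dtc_error("dtcprs_bad_input", "unnamed score vectors must have equal length")
    }
    a <- results_a
    b <- results_b
  }
  if (length(a) < 3L) {
    dtc_error("dtcprs_degenerate_input", "need at least 3 shared traits")
  }
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    dtc_error("dtcprs_degenerate_input", "scores have zero variance")
  }
  stats::cor(a, b)
}

#' Case/control predictive summary
#'
#' @param scores Numeric score per individual.
#' @param labels Binary outcome.
#' @return An `eval_result` with `nagelkerke_r2`, `auc`, `n_case`,
#'   `n_control`.
#' @export
evaluate_scores <- function(scores, labels) {
  y <- coerce_labels(labels)
  structure(
    list(nagelkerke_r2 = nagelkerke_r2(scores, y),
         auc = auc(scores, y),
         n_case = sum(y),
         n_control = length(y) - sum(y)),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> Nagelkerke R2 = %.4f, AUC = %.4f (%d cases / %d controls)\n",
              x$nagelkerke_r2, x$auc, x$n_case, x$n_control))
  invisible(x)
}
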