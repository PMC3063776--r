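#' Receiver operating characteristic curve
#'
#' Builds the ROC curve (sensitivity vs. 1-specificity) of a numeric risk
#' score against binary truth, sweeping the inclusive high-risk rule
#' `score >= threshold` over every distinct score, plus `Inf` (nobody called
#' high-risk).  The area under the curve is computed by the trapezoidal
#' rule, which for the empirical ROC equals the Mann-Whitney rank statistic
#' `U / (n1 * n0)` counting ties as 1/2.
#'
#' @param scores numeric risk scores (higher = more case-like).
#' @param labels binary truth, 1 = case, 0 = control.
#' @return An object of class `roc_curve` with components `thresholds`,
#'   `sensitivity`, `fpr` (1-specificity), `auc`, `n_cases`, `n_controls`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    stop("labels must contain both cases (1) and controls (0)", call. = FALSE)
  }
  thr <- c(sort(unique(scores)), Inf)
  s1 <- scores[labels == 1L]
  s0 <- scores[labels == 0L]
  sens <- vapply(thr, function(t) mean(s1 >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s0 >= t), numeric(1))
  # integrate in order of increasing fpr (thresholds decreasing)
  ord <- order(fpr, sens)
  x <- c(0, fpr[ord], 1)
  y <- c(0, sens[ord], 1)
  # at the lowest threshold everything is called high: fpr = sens = 1 already
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(
    list(thresholds = thr, sensitivity = sens, fpr = fpr, auc = auc,
         n_cases = length(s1), n_controls = length(s0)),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d cases vs %d controls, %d thresholds, AUC = %.3f\n",
              x$n_cases, x$n_controls, length(x$thresholds), x$auc))
  invisible(x)
}

#' AUC with a DeLong confidence interval
#'
#' Computes the area under the ROC curve as the Mann-Whitney statistic and
#' its confidence interval by DeLong's placement-value variance estimator.
#'
#' @param scores numeric risk scores.
#' @param labels binary truth, 1 = case, 0 = control.
#' @param conf confidence level, default 0.95.
#' @return A list with `auc`, `ci` (length-2 vector) and `se`.
#' @export
auc_ci <- function(scores, labels, conf = 0.95) {
  labels <- as.integer(labels)
  s1 <- scores[labels == 1L]
  s0 <- scores[labels == 0L]
  if (length(s1) == 0L || length(s0) == 0L) {
    stop("both classes required", call. = FALSE)
  }
  # placement values: for each case the fraction of controls it outranks
  v10 <- vapply(s1, function(x) mean((x > s0) + 0.5 * (x == s0)), numeric(1))
  v01 <- vapply(s0, function(x) mean((s1 > x) + 0.5 * (s1 == x)), numeric(1))
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / length(s1) + stats::var(v01) / length(s0))
  z <- qnorm(1 - (1 - conf) / 2)
  list(auc = auc,
       ci = c(max(0, auc - z * se), min(1, auc + z * se)),
       se = se)
}

#' Threshold maximizing the overall correct classification rate
#'
#' Scans every threshold on the ROC curve and returns the one that would
#' have correctly classified the greatest number of individuals
#' (`TP + TN`).  Ties are broken toward the higher threshold, i.e. the more
#' specific rule.
#'
#' @param curve a [roc_curve()].
#' @return The optimal threshold (a score value, or `Inf` when calling
#'   everyone low-risk is optimal).
#' @export
optimal_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  correct <- curve$sensitivity * curve$n_cases +
    (1 - curve$fpr) * curve$n_controls
  best <- which(correct == max(correct))
  max(curve$thresholds[best])
}
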