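#' Confusion counts of risk calls against clinician truth
#'
#' Tallies true/false positives and negatives among classified individuals
#' and, separately by true status, the individuals a method could not
#' classify (`"cnc"` calls).  A high-risk call for a true case is a true
#' positive.
#'
#' @param calls character vector of `"high"` / `"low"` / `"cnc"` calls.
#' @param truth binary truth, 1 = case, 0 = control.
#' @return An object of class `confusion_summary` with counts `tp`, `fp`,
#'   `tn`, `fn`, `n_cnc_case`, `n_cnc_control`.
#' @export
confusion_summary <- function(calls, truth) {
  if (length(calls) != length(truth)) {
    stop("calls and truth must have the same length", call. = FALSE)
  }
  if (!all(calls %in% c("high", "low", "cnc"))) {
    stop("calls must be 'high', 'low' or 'cnc'", call. = FALSE)
  }
  truth <- as.integer(truth)
  stopifnot(all(truth %in% c(0L, 1L)))
  structure(
    list(
      tp = sum(calls == "high" & truth == 1L),
      fp = sum(calls == "high" & truth == 0L),
      tn = sum(calls == "low" & truth == 0L),
      fn = sum(calls == "low" & truth == 1L),
      n_cnc_case = sum(calls == "cnc" & truth == 1L),
      n_cnc_control = sum(calls == "cnc" & truth == 0L)
    ),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FP %d  TN %d  FN %d  CNC cases %d  CNC controls %d\n",
              x$tp, x$fp, x$tn, x$fn, x$n_cnc_case, x$n_cnc_control))
  invisible(x)
}

rate_or_na <- function(num, den) if (den > 0) num / den else NA_real_

#' Classification metrics under dual denominators
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, `PPV = TP/(TP+FP)`,
#' `NPV = TN/(TN+FN)` and overall correct `(TP+TN)/n` computed among the
#' individuals the method could classify, together with "all-tested"
#' variants whose denominators include the could-not-classify individuals
#' (for example, 51 correct of 71 classifiable cases is a sensitivity of
#' 71.8%, but 51 of 87 total cases is 58.6%).  Rates with a zero
#' denominator are reported as `NA` (undefined), never as 0.
#'
#' @param conf a [confusion_summary()].
#' @return An object of class `metrics_report`: a list with elements
#'   `classified` and `all_tested` (each holding `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `overall_correct`) plus `cnc_rate`.
#'   PPV/NPV have no meaningful all-tested variant (a CNC individual is
#'   neither a high nor a low call) and are `NA` there.
#' @export
classification_metrics <- function(conf) {
  stopifnot(inherits(conf, "confusion_summary"))
  n_cases <- conf$tp + conf$fn + conf$n_cnc_case
  n_controls <- conf$tn + conf$fp + conf$n_cnc_control
  n_classified <- conf$tp + conf$fp + conf$tn + conf$fn
  n_total <- n_cases + n_controls
  structure(
    list(
      classified = list(
        sensitivity = rate_or_na(conf$tp, conf$tp + conf$fn),
        specificity = rate_or_na(conf$tn, conf$tn + conf$fp),
        ppv = rate_or_na(conf$tp, conf$tp + conf$fp),
        npv = rate_or_na(conf$tn, conf$tn + conf$fn),
        overall_correct = rate_or_na(conf$tp + conf$tn, n_classified)
      ),
      all_tested = list(
        sensitivity = rate_or_na(conf$tp, n_cases),
        specificity = rate_or_na(conf$tn, n_controls),
        ppv = NA_real_,
        npv = NA_real_,
        overall_correct = rate_or_na(conf$tp + conf$tn, n_total)
      ),
      cnc_rate = rate_or_na(conf$n_cnc_case + conf$n_cnc_control, n_total),
      confusion = conf
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(a, b) {
    if (is.na(b) || isTRUE(all.equal(a, b))) {
      sprintf("%.1f", 100 * a)
    } else {
      sprintf("%.1f (%.1f)", 100 * a, 100 * b)
    }
  }
  cat("classification rates, % (all-tested in parentheses where CNC occurs):\n")
  for (m in c("sensitivity", "specificity", "ppv", "npv", "overall_correct")) {
    cat(sprintf("  %-16s %s\n", m, fmt(x$classified[[m]], x$all_tested[[m]])))
  }
  if (!is.na(x$cnc_rate) && x$cnc_rate > 0) {
    cat(sprintf("  %-16s %.1f\n", "cnc_rate", 100 * x$cnc_rate))
  }
  invisible(x)
}

#' Prevalence-adjusted predictive values
#'
#' PPV and NPV estimated from case-control data reflect the sampling
#' case:control ratio, not the population prevalence, and are typically
#' inflated.  Bayes' rule re-expresses them at a chosen population
#' prevalence pi from the (prevalence-free) sensitivity S and specificity
#' P:
#'
#' \deqn{PPV = \frac{S \pi}{S \pi + (1 - P)(1 - \pi)}}
#' \deqn{NPV = \frac{P (1 - \pi)}{P (1 - \pi) + (1 - S) \pi}}
#'
#' When pi equals the sample case fraction these reduce to the unadjusted
#' values.
#'
#' @param sensitivity,specificity rates in (0, 1).
#' @param prevalence population prevalence in (0, 1).
#' @return A list with `prevalence`, `adjusted_ppv` and `adjusted_npv`.
#' @export
adjust_predictive_values <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity > 0, sensitivity < 1,
            specificity > 0, specificity < 1)
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  }
  ppv <- sensitivity * prevalence /
    (sensitivity * prevalence + (1 - specificity) * (1 - prevalence))
  npv <- specificity * (1 - prevalence) /
    (specificity * (1 - prevalence) + (1 - sensitivity) * prevalence)
  list(prevalence = prevalence, adjusted_ppv = ppv, adjusted_npv = npv)
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' `(n0, n1, n2)` against the proportions `(1-q)^2, 2q(1-q), q^2` expected
#' at the sample allele frequency `q = (n1 + 2 n2) / (2 n)`.  For a
#' monomorphic sample the test is undefined and `NA` statistics are
#' returned.
#'
#' @param counts integer vector `(n0, n1, n2)` of genotype counts (0, 1 and
#'   2 copies of the allele).
#' @return A list with `statistic`, `p_value`, `allele_freq` and `n`.
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0L) stop("no individuals", call. = FALSE)
  q <- (counts[2L] + 2 * counts[3L]) / (2 * n)
  if (q == 0 || q == 1) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                allele_freq = q, n = n))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
       allele_freq = q, n = n)
}

#' Format a metrics report as a publication-style table row
#'
#' Percentages with one decimal; where could-not-classify individuals
#' exist, the all-tested rate follows in parentheses, matching the layout
#' of the published classification tables.
#'
#' @param reports a named list of [classification_metrics()] reports, one
#'   per method.
#' @return A `data.frame` with character columns `Sensitivity`,
#'   `Specificity`, `PPV`, `NPV` and `Overall` and one row per method.
#' @export
metrics_table <- function(reports) {
  stopifnot(is.list(reports), length(reports) > 0L)
  fmt <- function(a, b) {
    if (is.na(a)) return("NA")
    if (is.na(b) || isTRUE(all.equal(a, b))) return(sprintf("%.1f", 100 * a))
    sprintf("%.1f (%.1f)", 100 * a, 100 * b)
  }
  rows <- lapply(reports, function(r) {
    has_cnc <- !is.na(r$cnc_rate) && r$cnc_rate > 0
    pick <- function(m) {
      fmt(r$classified[[m]], if (has_cnc) r$all_tested[[m]] else NA_real_)
    }
    data.frame(
      Sensitivity = pick("sensitivity"),
      Specificity = pick("specificity"),
      PPV = pick("ppv"),
      NPV = pick("npv"),
      Overall = pick("overall_correct"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(reports)
  out
}
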