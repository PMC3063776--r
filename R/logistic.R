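#' Construct a six-factor logistic risk model
#'
#' A logistic model is an intercept plus one coefficient per susceptibility
#' factor on the log-odds scale; the odds ratio of factor f is
#' `exp(coefficients[f])`.  Age enters per year, smoking as a 0/1 indicator,
#' and each SNP additively as a risk-allele count.
#'
#' @param intercept model constant on the log-odds scale.
#' @param coefficients named numeric vector holding one coefficient for each
#'   of [factor_names()].
#' @param fit optional fitted-model metadata (standard errors, p-values, CI);
#'   attached by [fit_logistic()].
#' @return An object of class `logistic_model`.
#' @export
logistic_model <- function(intercept, coefficients, fit = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients))
  missing_f <- setdiff(factor_names(), names(coefficients))
  if (length(missing_f) > 0L) {
    stop("coefficients missing for: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(intercept = intercept,
         coefficients = coefficients[factor_names()],
         fit = fit),
    class = "logistic_model"
  )
}

#' The published six-factor AMD risk model
#'
#' The clinic-based logistic model that the synthetic-cohort presets use as
#' their generative truth: constant -10.48, with per-year age 0.13, smoking
#' 0.48, CFH Y402H 1.04, ARMS2 A69S 0.69, CFB R32Q -1.10 (protective allele
#' counted) and C3 R102G 0.41, all on the log-odds scale.
#'
#' @return A [logistic_model()].
#' @export
amd_risk_model <- function() {
  logistic_model(
    intercept = -10.48,
    coefficients = c(age = 0.13, smoking = 0.48,
                     CFH = 1.04, ARMS2 = 0.69, CFB = -1.10, C3 = 0.41)
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Six-factor logistic AMD risk model\n")
  if (!is.null(x$fit)) {
    print(model_table(x), digits = 3)
  } else {
    cat(sprintf("  constant  %8.3f\n", x$intercept))
    for (f in factor_names()) {
      cat(sprintf("  %-8s %8.3f  (OR %.2f)\n", f, x$coefficients[[f]],
                  exp(x$coefficients[[f]])))
    }
  }
  invisible(x)
}

#' Fit the six-factor logistic model to a cohort
#'
#' Maximum-likelihood logistic regression of affection status on age,
#' smoking and the four additively coded genotypes, with no interaction
#' terms.  Fitting is by iteratively reweighted least squares via
#' [stats::glm()].  Complete separation (detectable as non-convergence or
#' exploding coefficients) is reported as an explicit error rather than
#' returned silently.
#'
#' @param cohort an `amd_cohort` containing both cases and controls with no
#'   missing factor values.
#' @return A [logistic_model()] whose `fit` element carries standard errors,
#'   Wald p-values, odds ratios and 95% confidence intervals per factor;
#'   see [model_table()].
#' @export
fit_logistic <- function(cohort) {
  stopifnot(inherits(cohort, "amd_cohort"))
  if (length(unique(cohort$status)) < 2L) {
    stop("cohort must contain both cases and controls", call. = FALSE)
  }
  if (anyNA(cohort[, factor_names()])) {
    stop("cohort has missing factor values; drop incomplete rows first",
         call. = FALSE)
  }
  form <- stats::as.formula(paste("status ~", paste(factor_names(), collapse = " + ")))
  g <- suppressWarnings(
    glm(form, family = binomial(), data = cohort,
        control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  if (!g$converged || any(abs(coef(g)) > 50)) {
    stop("logistic fit did not converge (possible complete separation)",
         call. = FALSE)
  }
  est <- coef(g)
  se <- sqrt(diag(vcov(g)))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  fit <- data.frame(
    term = names(est),
    coefficient = unname(est),
    se = unname(se),
    p_value = unname(p),
    odds_ratio = exp(unname(est)),
    ci_lower = exp(unname(est) - 1.96 * unname(se)),
    ci_upper = exp(unname(est) + 1.96 * unname(se)),
    stringsAsFactors = FALSE
  )
  logistic_model(
    intercept = unname(est[["(Intercept)"]]),
    coefficients = est[factor_names()],
    fit = fit
  )
}

#' Coefficient / odds-ratio table of a logistic model
#'
#' One row per factor plus the constant, with the coefficient, its standard
#' error, Wald p-value, odds ratio `exp(coefficient)` and 95% confidence
#' interval `exp(coefficient +/- 1.96 * SE)` where a fitted SE is available.
#'
#' @param model a [logistic_model()].
#' @return A `data.frame`.
#' @export
model_table <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  if (!is.null(model$fit)) {
    tab <- model$fit
    tab$term[tab$term == "(Intercept)"] <- "constant"
    tab$odds_ratio[tab$term == "constant"] <- NA_real_
    tab$ci_lower[tab$term == "constant"] <- NA_real_
    tab$ci_upper[tab$term == "constant"] <- NA_real_
    return(tab)
  }
  data.frame(
    term = c(factor_names(), "constant"),
    coefficient = c(unname(model$coefficients), model$intercept),
    odds_ratio = c(exp(unname(model$coefficients)), NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Disease probability under a logistic model
#'
#' Computes `p = 1 / (1 + exp(-(intercept + sum(coefficient * value))))` for
#' each individual: the model's rough estimate of the probability of AMD.
#'
#' @param model a [logistic_model()].
#' @param newdata a data frame with one column per factor in
#'   [factor_names()]; individuals with a missing factor raise an error (the
#'   classifiers require complete risk-factor information).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, newdata) {
  stopifnot(inherits(model, "logistic_model"), is.data.frame(newdata))
  missing_f <- setdiff(factor_names(), names(newdata))
  if (length(missing_f) > 0L) {
    stop("newdata missing factors: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(newdata[, factor_names(), drop = FALSE])
  if (anyNA(X)) {
    stop("missing factor values; individuals without complete data cannot be scored",
         call. = FALSE)
  }
  lp <- model$intercept + drop(X %*% model$coefficients)
  plogis(lp)
}

#' Threshold a disease probability into a risk call
#'
#' Individuals with probability at or above the threshold are called
#' `"high"` risk, all others `"low"`; the comparison is inclusive (p equal
#' to the threshold is high-risk).
#'
#' @param p numeric vector of probabilities.
#' @param threshold classification cutoff in (0, 1).
#' @return Character vector of `"high"` / `"low"` calls.
#' @export
classify_prob <- function(p, threshold = 0.5) {
  stopifnot(is.numeric(p), threshold > 0, threshold < 1)
  ifelse(p >= threshold, "high", "low")
}

#' Serialize a logistic model to a plain-text key-value file
#'
#' @param model a [logistic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logistic <- function(model, path) {
  stopifnot(inherits(model, "logistic_model"))
  tab <- model_table(model)
  write.table(format(tab, digits = 10), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a logistic model written by [write_logistic()]
#'
#' @param path input path.
#' @return A [logistic_model()].
#' @export
read_logistic <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "coefficient") %in% names(tab)))
  ic <- tab$coefficient[tab$term == "constant"]
  co <- tab$coefficient[tab$term != "constant"]
  names(co) <- tab$term[tab$term != "constant"]
  logistic_model(intercept = ic, coefficients = co)
}
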