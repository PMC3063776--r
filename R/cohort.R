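#' Specify a synthetic case-control cohort
#'
#' A cohort specification bundles everything needed to simulate a
#' clinic-ascertained AMD case-control sample: the case and control quotas,
#' the risk-allele frequencies of the four SNPs (genotypes are drawn under
#' Hardy-Weinberg equilibrium), the age distribution (normal, truncated to
#' 50-100 years), the smoking prevalence, and a six-factor logistic model
#' that acts as the generative truth relating the factors to disease.
#'
#' @param n_cases,n_controls non-negative case and control quotas.
#' @param risk_allele_freq named numeric vector of risk-allele frequencies in
#'   `[0,1]` for `snp_names()`.
#' @param age_mean,age_sd mean and standard deviation (years) of the age
#'   distribution before truncation; `age_sd` must be positive.
#' @param smoking_prevalence probability of being an ever-smoker.
#' @param true_model a [logistic_model()] used as the generative truth.
#' @param seed integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [cohort_preset()]
#' @export
cohort_spec <- function(n_cases, n_controls, risk_allele_freq,
                        age_mean, age_sd, smoking_prevalence,
                        true_model, seed = 1L) {
  stopifnot(
    length(n_cases) == 1L, length(n_controls) == 1L,
    n_cases >= 0, n_controls >= 0,
    is.numeric(risk_allele_freq),
    all(snp_names() %in% names(risk_allele_freq)),
    all(risk_allele_freq >= 0 & risk_allele_freq <= 1),
    age_sd > 0,
    smoking_prevalence >= 0, smoking_prevalence <= 1,
    inherits(true_model, "logistic_model")
  )
  structure(
    list(
      n_cases = as.integer(n_cases),
      n_controls = as.integer(n_controls),
      risk_allele_freq = risk_allele_freq[snp_names()],
      age_mean = age_mean,
      age_sd = age_sd,
      smoking_prevalence = smoking_prevalence,
      true_model = true_model,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic AMD cohort specification\n")
  cat(sprintf("  cases: %d  controls: %d  seed: %d\n",
              x$n_cases, x$n_controls, x$seed))
  cat(sprintf("  age ~ N(%.1f, %.1f) truncated to [50, 100]; smoking prevalence %.3f\n",
              x$age_mean, x$age_sd, x$smoking_prevalence))
  cat("  risk-allele frequencies:\n")
  for (s in snp_names()) {
    cat(sprintf("    %-6s %.3f\n", s, x$risk_allele_freq[[s]]))
  }
  invisible(x)
}

#' Preset cohort specifications
#'
#' Ready-made specifications mirroring the three published case-control
#' samples that motivated this package: a clinic-based training sample of
#' 349 cases and 216 controls (`"vm_training"`), its held-out fifth
#' (`"vm_testing"`, 87 cases / 54 controls), and a primarily population-based
#' elderly sample (`"arma"`, 85 cases / 148 controls).  Allele frequencies,
#' age means/SDs and smoking prevalences are the published sample
#' characteristics; the generative truth is the published six-factor
#' logistic model ([amd_risk_model()]).
#'
#' @param name one of `"vm_training"`, `"vm_testing"`, `"arma"`.
#' @param seed integer seed stored in the returned specification.
#' @return A [cohort_spec()].
#' @export
cohort_preset <- function(name = c("vm_training", "vm_testing", "arma"),
                          seed = 1L) {
  name <- match.arg(name)
  pars <- switch(name,
    vm_training = list(
      n_cases = 349L, n_controls = 216L,
      freq = c(CFH = 0.506, ARMS2 = 0.357, CFB = 0.068, C3 = 0.253),
      age_mean = 73.5, age_sd = 8.4, smoking = 0.520
    ),
    vm_testing = list(
      n_cases = 87L, n_controls = 54L,
      freq = c(CFH = 0.489, ARMS2 = 0.312, CFB = 0.071, C3 = 0.262),
      age_mean = 73.1, age_sd = 8.3, smoking = 0.560
    ),
    arma = list(
      n_cases = 85L, n_controls = 148L,
      freq = c(CFH = 0.429, ARMS2 = 0.238, CFB = 0.097, C3 = 0.255),
      age_mean = 79.3, age_sd = 3.6, smoking = 0.502
    )
  )
  cohort_spec(
    n_cases = pars$n_cases, n_controls = pars$n_controls,
    risk_allele_freq = pars$freq,
    age_mean = pars$age_mean, age_sd = pars$age_sd,
    smoking_prevalence = pars$smoking,
    true_model = amd_risk_model(),
    seed = seed
  )
}

#' Sample additive genotypes under Hardy-Weinberg equilibrium
#'
#' Draws risk-allele counts 0/1/2 with probabilities (1-q)^2, 2q(1-q), q^2
#' where q is the risk-allele frequency, i.e. a Binomial(2, q) draw per
#' individual.
#'
#' @param freq risk-allele frequency in `[0,1]`.
#' @param n number of individuals to draw.
#' @return Integer vector of risk-allele counts in `{0, 1, 2}`.
#' @export
sample_genotype <- function(freq, n = 1L) {
  if (!is.numeric(freq) || length(freq) != 1L || is.na(freq) ||
      freq < 0 || freq > 1) {
    stop("`freq` must be a single allele frequency in [0, 1]", call. = FALSE)
  }
  rbinom(n, size = 2L, prob = freq)
}

# Draw a batch of covariate vectors from the spec's population model.
draw_covariates <- function(spec, n) {
  age <- rnorm(n, spec$age_mean, spec$age_sd)
  # truncate by redrawing: ages are exam ages of an elderly cohort
  bad <- which(age < 50 | age > 100)
  while (length(bad) > 0L) {
    age[bad] <- rnorm(length(bad), spec$age_mean, spec$age_sd)
    bad <- bad[age[bad] < 50 | age[bad] > 100]
  }
  d <- data.frame(
    age = age,
    smoking = rbinom(n, 1L, spec$smoking_prevalence)
  )
  for (s in snp_names()) {
    d[[s]] <- sample_genotype(spec$risk_allele_freq[[s]], n)
  }
  d
}

#' Generate a synthetic case-control cohort
#'
#' Simulates a clinic-ascertained sample with fixed case and control quotas
#' by case-control rejection sampling: covariate vectors are drawn from the
#' population model in `spec`, each is assigned a disease probability p by
#' the generative logistic model, and a Bernoulli(p) draw routes it to the
#' case pool (on success) or the control pool (on failure).  Pools that have
#' reached quota discard further arrivals.  The procedure is fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param max_attempts cap on total covariate draws before giving up (guards
#'   against generative models that make one class essentially unreachable).
#' @return A `data.frame` of class `amd_cohort` with columns `id`, `age`,
#'   `smoking`, `CFH`, `ARMS2`, `CFB`, `C3`, `status` (1 = case,
#'   0 = control).
#' @export
generate_cohort <- function(spec, max_attempts = 1e6) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cases <- vector("list", 0L)
  controls <- vector("list", 0L)
  n_case <- 0L
  n_control <- 0L
  attempts <- 0L
  batch <- max(256L, 2L * (spec$n_cases + spec$n_controls))
  while (n_case < spec$n_cases || n_control < spec$n_controls) {
    if (attempts >= max_attempts) {
      stop(sprintf(
        "cohort quotas unreachable: %d/%d cases, %d/%d controls after %d draws",
        n_case, spec$n_cases, n_control, spec$n_controls, attempts
      ), call. = FALSE)
    }
    d <- draw_covariates(spec, batch)
    attempts <- attempts + batch
    p <- predict_prob(spec$true_model, d)
    is_case <- runif(batch) < p
    if (n_case < spec$n_cases) {
      take <- d[is_case, , drop = FALSE]
      take <- take[seq_len(min(nrow(take), spec$n_cases - n_case)), , drop = FALSE]
      cases[[length(cases) + 1L]] <- take
      n_case <- n_case + nrow(take)
    }
    if (n_control < spec$n_controls) {
      take <- d[!is_case, , drop = FALSE]
      take <- take[seq_len(min(nrow(take), spec$n_controls - n_control)), , drop = FALSE]
      controls[[length(controls) + 1L]] <- take
      n_control <- n_control + nrow(take)
    }
  }
  out <- rbind(
    do.call(rbind, cases),
    do.call(rbind, controls)
  )
  out$status <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  as_amd_cohort(out)
}

#' Coerce a data frame to a validated cohort table
#'
#' Checks that all six factors and the affection status are present and
#' within their domains: genotypes in `{0,1,2}`, smoking and status in
#' `{0,1}`, ages positive.
#'
#' @param x a `data.frame` with columns `age`, `smoking`, `CFH`, `ARMS2`,
#'   `CFB`, `C3`, `status`, and optionally `id`.
#' @return The same data with class `amd_cohort` prepended.
#' @export
as_amd_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c(factor_names(), "status")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"id" %in% names(x)) x <- cbind(id = seq_len(nrow(x)), x)
  for (s in snp_names()) {
    if (!all(x[[s]] %in% c(0L, 1L, 2L))) {
      stop(sprintf("column %s has genotypes outside {0,1,2}", s), call. = FALSE)
    }
  }
  if (!all(x$smoking %in% c(0L, 1L))) {
    stop("column smoking must be 0/1", call. = FALSE)
  }
  if (!all(x$status %in% c(0L, 1L))) {
    stop("column status must be 0 (control) / 1 (case)", call. = FALSE)
  }
  if (any(x$age <= 0)) stop("ages must be positive", call. = FALSE)
  x <- x[, c("id", needed)]
  class(x) <- unique(c("amd_cohort", class(x)))
  x
}

#' Write a cohort table to TSV
#'
#' @param cohort an `amd_cohort` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "amd_cohort"))
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from TSV (or CSV)
#'
#' Reads a per-individual factor table with header columns `id`, `age`,
#' `smoking`, `CFH`, `ARMS2`, `CFB`, `C3`, `status`.  Rows with a missing
#' value in any required column are dropped with a message giving the count,
#' mirroring the complete-case requirement of the classifiers; genotype
#' values outside `{0,1,2}` are a parse error naming the row and column.
#'
#' @param path input file; tab-separated by default, comma-separated files
#'   are detected from the header line.
#' @return An `amd_cohort` data frame.
#' @export
read_cohort <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  needed <- c(factor_names(), "status")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    stop("malformed cohort header, missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in needed) {
    if (!is.numeric(x[[col]])) {
      bad <- which(!is.na(x[[col]]) & is.na(suppressWarnings(as.numeric(x[[col]]))))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value in column %s, row %d", col, bad[1L]),
             call. = FALSE)
      }
      x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
    }
  }
  incomplete <- !stats::complete.cases(x[, needed])
  if (any(incomplete)) {
    message(sprintf("read_cohort: dropped %d row(s) with missing factor values",
                    sum(incomplete)))
    x <- x[!incomplete, , drop = FALSE]
  }
  for (s in snp_names()) {
    bad <- which(!x[[s]] %in% c(0, 1, 2))
    if (length(bad) > 0L) {
      stop(sprintf("genotype outside {0,1,2} in column %s, row %d", s, bad[1L]),
           call. = FALSE)
    }
  }
  as_amd_cohort(x)
}

#' Stratified train/test split of a cohort
#'
#' Randomly assigns `round(fraction * n)` individuals of each affection
#' status to the training set and the remainder to the testing set, so that
#' the case:control ratio is preserved (e.g. a 4/5 split of 436 cases yields
#' 349 training cases).
#'
#' @param cohort an `amd_cohort`.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return A list with elements `training` and `testing`, both `amd_cohort`.
#' @export
split_cohort <- function(cohort, fraction, seed = 1L) {
  stopifnot(inherits(cohort, "amd_cohort"), fraction > 0, fraction < 1)
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (st in c(1L, 0L)) {
    idx <- which(cohort$status == st)
    n_train <- round(fraction * length(idx))
    if (n_train == 0L || n_train == length(idx)) {
      stop(sprintf("stratum with status %d too small to split at fraction %.3f",
                   st, fraction), call. = FALSE)
    }
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  list(
    training = as_amd_cohort(cohort[sort(train_idx), , drop = FALSE]),
    testing = as_amd_cohort(cohort[-sort(train_idx), , drop = FALSE])
  )
}
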