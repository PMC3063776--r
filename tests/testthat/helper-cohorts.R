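# fixtures built in code: no data files

# small random cohort with no particular genotype-phenotype structure
toy_cohort <- function(n = 60, seed = 1) {
  set.seed(seed)
  as_amd_cohort(data.frame(
    age = runif(n, 55, 95),
    smoking = rbinom(n, 1, 0.5),
    CFH = rbinom(n, 2, 0.5),
    ARMS2 = rbinom(n, 2, 0.35),
    CFB = rbinom(n, 2, 0.1),
    C3 = rbinom(n, 2, 0.25),
    status = rbinom(n, 1, 0.5)
  ))
}

# cohort whose status is a deterministic step function of the CFH genotype;
# the other five factors are pure noise
single_factor_cohort <- function(seed, n = 500, permute = FALSE) {
  set.seed(seed)
  d <- data.frame(
    age = runif(n, 55, 95),
    smoking = rbinom(n, 1, 0.5),
    CFH = rbinom(n, 2, 0.5),
    ARMS2 = rbinom(n, 2, 0.35),
    CFB = rbinom(n, 2, 0.1),
    C3 = rbinom(n, 2, 0.25)
  )
  d$status <- as.integer(d$CFH >= 1)
  if (permute) d$status <- sample(d$status)
  as_amd_cohort(d)
}

# a logistic model with chosen coefficients, zeros elsewhere
toy_model <- function(intercept = 0, ...) {
  co <- setNames(numeric(6), factor_names())
  override <- c(...)
  co[names(override)] <- override
  logistic_model(intercept, co)
}

# published 95% CI bounds of the six factor odds ratios (training fit)
published_or_ci <- function() {
  rbind(age = c(1.10, 1.17), smoking = c(1.06, 2.45), CFH = c(2.07, 3.90),
        ARMS2 = c(1.47, 2.72), CFB = c(0.18, 0.60), C3 = c(1.09, 2.11))
}

# brute-force MDR re-count: classify each test individual by re-counting the
# raw training table, independently of the mdr_model cell machinery
mdr_oracle <- function(training, testing, k = 4L) {
  b <- age_binning(training$age, k)
  tr_key <- paste(bin_age(b, training$age), training$smoking,
                  training$CFH, training$ARMS2, training$CFB, training$C3)
  te_key <- paste(bin_age(b, testing$age), testing$smoking,
                  testing$CFH, testing$ARMS2, testing$CFB, testing$C3)
  overall <- sum(training$status == 1) / sum(training$status == 0)
  vapply(te_key, function(k_) {
    hit <- tr_key == k_
    if (!any(hit)) return("cnc")
    nca <- sum(training$status[hit] == 1)
    nco <- sum(training$status[hit] == 0)
    if (nco == 0) {
      if (nca > 0) "high" else "cnc"
    } else if (nca / nco > overall) "high" else "low"
  }, character(1), USE.NAMES = FALSE)
}

# Mann-Whitney AUC by direct pairwise counting (ties as 1/2)
rank_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, ">") + 0.5 * outer(s1, s0, "==")
  mean(cmp)
}

# exhaustive accuracy scan over every candidate threshold (>= rule),
# ties broken toward the higher threshold
threshold_oracle <- function(scores, labels) {
  cands <- c(sort(unique(scores)), Inf)
  correct <- vapply(cands, function(t) {
    sum((scores >= t) == (labels == 1))
  }, numeric(1))
  max(cands[correct == max(correct)])
}
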