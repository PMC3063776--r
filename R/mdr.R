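#' Quantile binning of age learned from a training cohort
#'
#' MDR and the evolved neural networks use age coded as its training-set
#' quantile ("1" for the lowest quantile of age at exam, "2" for the second,
#' and so on).  Bin edges are the type-1 (order-statistic) quantiles of the
#' training ages, so that bin occupancy on the training set is balanced to
#' within one individual when ages are distinct.  Test ages are always
#' binned with the training-derived edges - never re-quantiled - and ages
#' outside the training range clamp to the extreme bins.
#'
#' @param training_ages numeric vector of training ages.
#' @param k number of quantile bins (default 4, quartiles); `k = 1` puts
#'   every age in one bin, removing age from the factor combinations.
#' @return An object of class `age_binning` with `k` and `edges` (the k-1
#'   internal cut points).
#' @export
age_binning <- function(training_ages, k = 4L) {
  stopifnot(is.numeric(training_ages), length(training_ages) > 0L, k >= 1L)
  if (k == 1L) {
    return(structure(list(k = 1L, edges = numeric(0)), class = "age_binning"))
  }
  if (length(unique(training_ages)) < 2L) {
    stop("training ages are all identical; quantile bins undefined",
         call. = FALSE)
  }
  edges <- unname(quantile(training_ages, probs = seq_len(k - 1L) / k, type = 1))
  if (any(diff(edges) < 0)) stop("quantile edges not ordered", call. = FALSE)
  structure(list(k = as.integer(k), edges = edges), class = "age_binning")
}

#' Map ages to their training-derived quantile bin
#'
#' @param binning an [age_binning()].
#' @param age numeric vector of ages.
#' @return Integer bin indices in `1..k`; bins are right-closed
#'   (`age <= edges[1]` is bin 1).
#' @export
bin_age <- function(binning, age) {
  stopifnot(inherits(binning, "age_binning"))
  idx <- findInterval(age, binning$edges, left.open = TRUE) + 1L
  pmin(pmax(idx, 1L), binning$k)
}

mdr_key <- function(age_bin, smoking, genotypes) {
  paste(age_bin, smoking,
        genotypes[[1L]], genotypes[[2L]], genotypes[[3L]], genotypes[[4L]],
        sep = "|")
}

cohort_keys <- function(cohort, binning) {
  mdr_key(bin_age(binning, cohort$age), cohort$smoking,
          cohort[, snp_names(), drop = FALSE])
}

#' Build the MDR cell-ratio classifier from a training cohort
#'
#' Enumerates every susceptibility-factor combination (age quantile bin,
#' smoking, and the four genotypes) observed in training, counts the cases
#' and controls in each cell, and labels a cell high-risk exactly when its
#' case:control ratio strictly exceeds the overall training case:control
#' ratio.  Cells with controls but no cases are low-risk; cells with cases
#' but no controls are high-risk (an infinite ratio exceeds any finite
#' overall ratio).
#'
#' @param cohort an `amd_cohort` with at least one case and one control.
#' @param k number of age quantile bins (default 4).
#' @return An object of class `mdr_model` with the cell table, the overall
#'   case:control ratio and the [age_binning()] learned from training.
#' @export
mdr_build <- function(cohort, k = 4L) {
  stopifnot(inherits(cohort, "amd_cohort"))
  n_case <- sum(cohort$status == 1L)
  n_control <- sum(cohort$status == 0L)
  if (n_case == 0L || n_control == 0L) {
    stop("training cohort must contain both cases and controls", call. = FALSE)
  }
  binning <- age_binning(cohort$age, k)
  key <- cohort_keys(cohort, binning)
  case_count <- tapply(cohort$status == 1L, key, sum)
  control_count <- tapply(cohort$status == 0L, key, sum)
  overall_ratio <- n_case / n_control
  # strict comparison: a cell ratio equal to the overall ratio is low-risk
  high <- ifelse(control_count == 0L,
                 case_count > 0L,
                 case_count / control_count > overall_ratio)
  parts <- do.call(rbind, strsplit(names(case_count), "|", fixed = TRUE))
  cells <- data.frame(
    age_bin = as.integer(parts[, 1L]),
    smoking = as.integer(parts[, 2L]),
    CFH = as.integer(parts[, 3L]),
    ARMS2 = as.integer(parts[, 4L]),
    CFB = as.integer(parts[, 5L]),
    C3 = as.integer(parts[, 6L]),
    n_case = as.integer(case_count),
    n_control = as.integer(control_count),
    label = ifelse(high, "high", "low"),
    stringsAsFactors = FALSE
  )
  rownames(cells) <- NULL
  cells <- cells[order(cells$age_bin, cells$smoking, cells$CFH, cells$ARMS2,
                       cells$CFB, cells$C3), , drop = FALSE]
  structure(
    list(cells = cells, overall_ratio = overall_ratio, binning = binning,
         n_case = n_case, n_control = n_control),
    class = "mdr_model"
  )
}

#' @export
print.mdr_model <- function(x, ...) {
  cat(sprintf(
    "MDR model: %d cells (%d high-risk), overall case:control ratio %.3f (%d:%d), %d age bins\n",
    nrow(x$cells), sum(x$cells$label == "high"), x$overall_ratio,
    x$n_case, x$n_control, x$binning$k))
  invisible(x)
}

#' Classify individuals with an MDR model
#'
#' Each individual receives the label of the training cell matching their
#' factor combination.  Combinations never observed in training have no
#' decision rule: those individuals are returned as `"cnc"` (could not
#' classify).
#'
#' @param model an [mdr_build()] model.
#' @param cohort an `amd_cohort` of individuals to classify.
#' @return Character vector of `"high"` / `"low"` / `"cnc"` calls.
#' @export
mdr_classify <- function(model, cohort) {
  stopifnot(inherits(model, "mdr_model"), inherits(cohort, "amd_cohort"))
  key <- cohort_keys(cohort, model$binning)
  cell_key <- mdr_key(model$cells$age_bin, model$cells$smoking,
                      model$cells[, snp_names(), drop = FALSE])
  m <- match(key, cell_key)
  ifelse(is.na(m), "cnc", model$cells$label[m])
}

#' Serialize an MDR model to TSV
#'
#' One row per cell (age_bin, smoking, four genotypes, case and control
#' counts, label); the overall ratio and binning are stored in commented
#' header lines.
#'
#' @param model an `mdr_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mdr <- function(model, path) {
  stopifnot(inherits(model, "mdr_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# overall_ratio\t%.12g", model$overall_ratio),
    sprintf("# n_case\t%d", model$n_case),
    sprintf("# n_control\t%d", model$n_control),
    sprintf("# age_k\t%d", model$binning$k),
    sprintf("# age_edges\t%s", paste(model$binning$edges, collapse = ","))
  ), con)
  write.table(model$cells, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an MDR model written by [write_mdr()]
#'
#' @param path input path.
#' @return An `mdr_model`.
#' @export
read_mdr <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  val <- function(name) {
    ln <- hdr[startsWith(hdr, paste0("# ", name, "\t"))]
    sub(".*\t", "", ln)
  }
  cells <- read.delim(textConnection(lines[!startsWith(lines, "# ")]),
                      stringsAsFactors = FALSE)
  binning <- structure(
    list(k = as.integer(val("age_k")),
         edges = as.numeric(strsplit(val("age_edges"), ",")[[1L]])),
    class = "age_binning"
  )
  structure(
    list(cells = cells,
         overall_ratio = as.numeric(val("overall_ratio")),
         binning = binning,
         n_case = as.integer(val("n_case")),
         n_control = as.integer(val("n_control"))),
    class = "mdr_model"
  )
}
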