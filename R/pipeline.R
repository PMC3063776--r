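#' Configure an end-to-end train/test/evaluate pipeline
#'
#' Reproduces the study design: train the requested classifiers on one
#' cohort, apply them (plus consensus combinations) to one or more
#' independent testing cohorts, and score every call vector against
#' clinician-assigned status, including prevalence-adjusted predictive
#' values.
#'
#' @param training an `amd_cohort`, a [cohort_spec()], or a preset name
#'   accepted by [cohort_preset()].
#' @param testing a named list of testing cohorts (same accepted forms).
#' @param methods subset of `c("logistic", "mdr", "genn")`.
#' @param thresholds logistic probability thresholds in (0, 1) to evaluate;
#'   the string `"optimal"` may be included to add the ROC-optimal
#'   threshold determined on the testing cohort.
#' @param age_bins number of age quantile bins for MDR and GENN.
#' @param genn list of overrides passed to [genn_config()] (e.g.
#'   `list(pop_size = 500, generations = 30)`).
#' @param prevalences population prevalences for adjusted PPV/NPV.
#' @param seed master seed; component seeds derive from it via
#'   [derive_seed()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(training, testing, methods = c("logistic", "mdr", "genn"),
                            thresholds = c(0.5), age_bins = 4L,
                            genn = list(), prevalences = c(0.055, 0.15),
                            seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  num_thr <- suppressWarnings(as.numeric(setdiff(thresholds, "optimal")))
  stopifnot(length(methods) >= 1L, !anyNA(num_thr),
            all(num_thr > 0 & num_thr < 1))
  if (!is.list(testing)) testing <- list(testing = testing)
  if (is.null(names(testing)) || any(names(testing) == "")) {
    names(testing) <- paste0("testing", seq_along(testing))
  }
  structure(
    list(training = training, testing = testing, methods = methods,
         thresholds = thresholds, age_bins = as.integer(age_bins),
         genn = genn, prevalences = prevalences, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

resolve_cohort <- function(x, seed) {
  if (inherits(x, "amd_cohort")) return(x)
  if (is.character(x) && length(x) == 1L) x <- cohort_preset(x, seed = seed)
  if (inherits(x, "cohort_spec")) {
    x$seed <- seed
    return(generate_cohort(x))
  }
  stop("cannot interpret cohort input of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' Run the full train/test/consensus/evaluate pipeline
#'
#' Trains each requested method on the training cohort and, for every
#' testing cohort, produces per-method calls, consensus calls (all three
#' methods and logistic+GENN, at each logistic threshold), a metrics
#' report per call vector, prevalence-adjusted predictive values, and ROC
#' summaries of the logistic scores.  Fully deterministic given the master
#' seed.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `models`
#'   (fitted classifiers), `evaluations` (per testing cohort: calls,
#'   metrics, adjusted predictive values, ROC) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  training <- resolve_cohort(config$training, derive_seed(config$seed, "training"))
  testing <- lapply(seq_along(config$testing), function(i) {
    resolve_cohort(config$testing[[i]],
                   derive_seed(config$seed, paste0("testing_", names(config$testing)[i])))
  })
  names(testing) <- names(config$testing)

  binning <- age_binning(training$age, config$age_bins)
  models <- list()
  if ("logistic" %in% config$methods) {
    models$logistic <- fit_logistic(training)
  }
  if ("mdr" %in% config$methods) {
    models$mdr <- mdr_build(training, k = config$age_bins)
  }
  if ("genn" %in% config$methods) {
    gc_args <- config$genn
    gc_args$seed <- derive_seed(config$seed, "genn")
    models$genn <- genn_evolve(training, do.call(genn_config, gc_args),
                               binning = binning)
  }

  evaluations <- lapply(names(testing), function(nm) {
    cohort <- testing[[nm]]
    truth <- cohort$status
    calls <- list()
    roc <- NULL
    if ("logistic" %in% config$methods) {
      p <- predict_prob(models$logistic, cohort)
      roc <- roc_curve(p, truth)
      thr <- config$thresholds
      if ("optimal" %in% thr) {
        thr <- c(setdiff(thr, "optimal"), optimal_threshold(roc))
      }
      thr <- as.numeric(thr)
      for (t in thr) {
        calls[[sprintf("logistic_%.3g", t)]] <- classify_prob(p, t)
      }
    }
    if ("mdr" %in% config$methods) {
      calls$mdr <- mdr_classify(models$mdr, cohort)
    }
    if ("genn" %in% config$methods) {
      calls$genn <- genn_classify(models$genn$network, cohort, binning)
    }
    lr_names <- grep("^logistic_", names(calls), value = TRUE)
    if (length(config$methods) == 3L) {
      for (ln in lr_names) {
        calls[[paste0("consensus_all_", ln)]] <-
          consensus_call(cbind(calls[[ln]], calls$mdr, calls$genn))
      }
    }
    if (all(c("logistic", "genn") %in% config$methods)) {
      for (ln in lr_names) {
        calls[[paste0("consensus_lr_genn_", ln)]] <-
          consensus_call(cbind(calls[[ln]], calls$genn))
      }
    }
    metrics <- lapply(calls, function(cl) {
      classification_metrics(confusion_summary(cl, truth))
    })
    adjusted <- lapply(metrics, function(m) {
      lapply(config$prevalences, function(pi) {
        s <- m$classified$sensitivity
        p <- m$classified$specificity
        if (is.na(s) || is.na(p) || s <= 0 || s >= 1 || p <= 0 || p >= 1) {
          return(NULL)
        }
        adjust_predictive_values(s, p, pi)
      })
    })
    list(cohort = cohort, calls = calls, metrics = metrics,
         adjusted = adjusted, roc = roc)
  })
  names(evaluations) <- names(testing)

  structure(
    list(models = models, training = training, evaluations = evaluations,
         config = config),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("AMD risk pipeline: methods [%s], %d testing cohort(s)\n",
              paste(x$config$methods, collapse = ", "),
              length(x$evaluations)))
  for (nm in names(x$evaluations)) {
    ev <- x$evaluations[[nm]]
    cat(sprintf("\n== %s (%d cases / %d controls) ==\n", nm,
                sum(ev$cohort$status == 1L), sum(ev$cohort$status == 0L)))
    print(metrics_table(ev$metrics))
    if (!is.null(ev$roc)) {
      cat(sprintf("logistic AUC: %.3f\n", ev$roc$auc))
    }
  }
  invisible(x)
}

#' Write pipeline reports to a directory
#'
#' Emits, per testing cohort: a classification-rate table
#' (`<name>_metrics.tsv`), adjusted predictive values
#' (`<name>_adjusted.tsv`), per-individual calls (`<name>_calls.tsv`) and
#' logistic ROC points (`<name>_roc.tsv`), plus the fitted logistic model
#' table and the MDR cell table where those methods ran.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$models$logistic)) {
    write_logistic(result$models$logistic, file.path(dir, "logistic_model.tsv"))
  }
  if (!is.null(result$models$mdr)) {
    write_mdr(result$models$mdr, file.path(dir, "mdr_model.tsv"))
  }
  if (!is.null(result$models$genn)) {
    write_genn(result$models$genn, file.path(dir, "genn_model.txt"))
  }
  for (nm in names(result$evaluations)) {
    ev <- result$evaluations[[nm]]
    tab <- metrics_table(ev$metrics)
    write.table(cbind(method = rownames(tab), tab),
                file.path(dir, paste0(nm, "_metrics.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    adj_rows <- list()
    for (m in names(ev$adjusted)) {
      for (a in ev$adjusted[[m]]) {
        if (is.null(a)) next
        adj_rows[[length(adj_rows) + 1L]] <- data.frame(
          method = m, prevalence = a$prevalence,
          adjusted_ppv = sprintf("%.1f", 100 * a$adjusted_ppv),
          adjusted_npv = sprintf("%.1f", 100 * a$adjusted_npv),
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(adj_rows) > 0L) {
      write.table(do.call(rbind, adj_rows),
                  file.path(dir, paste0(nm, "_adjusted.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    calls_df <- data.frame(id = ev$cohort$id, status = ev$cohort$status,
                           ev$calls, check.names = FALSE,
                           stringsAsFactors = FALSE)
    write.table(calls_df, file.path(dir, paste0(nm, "_calls.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ev$roc)) {
      roc_df <- data.frame(threshold = ev$roc$thresholds,
                           sensitivity = ev$roc$sensitivity,
                           fpr = ev$roc$fpr)
      write.table(roc_df, file.path(dir, paste0(nm, "_roc.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
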