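#' Sensitivity and specificity of a one-vs-rest prediction
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) for the dichotomy
#' `positive_class` vs everything else. An undefined denominator yields 0
#' with a warning.
#'
#' @param pred Named predicted labels.
#' @param truth Named true labels over the same samples.
#' @param positive_class Positive class (must occur in `truth`).
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sensitivity_specificity <- function(pred, truth, positive_class) {
  ids <- names(truth)
  if (is.null(ids) || !all(ids %in% names(pred))) {
    stop("`pred` and `truth` must be named over identical samples", call. = FALSE)
  }
  pred <- pred[ids]
  if (!positive_class %in% truth) {
    stop("positive class '", positive_class, "' absent from truth", call. = FALSE)
  }
  pos <- truth == positive_class
  ppos <- pred == positive_class
  tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
  tn <- sum(!pos & !ppos); fp <- sum(!pos & ppos)
  sens <- if (tp + fn == 0) { warning("no positive samples; sensitivity set to 0"); 0 } else tp / (tp + fn)
  spec <- if (tn + fp == 0) { warning("no negative samples; specificity set to 0"); 0 } else tn / (tn + fp)
  c(sensitivity = sens, specificity = spec)
}

#' Harmonic mean of sensitivity and specificity
#'
#' The accuracy summary used throughout: `2*s*p/(s+p)`, which is 0 whenever
#' `s + p = 0`. Note this is *not* the precision/recall F1.
#'
#' @param sensitivity,specificity Values in \[0, 1\].
#' @return Numeric in \[0, 1\].
#' @export
f_sens_spec <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  ifelse(sensitivity + specificity == 0, 0,
         2 * sensitivity * specificity / (sensitivity + specificity))
}

#' Per-class evaluation of multiclass predictions
#'
#' One-vs-rest sensitivity, specificity and F-score for every class present
#' in the truth, plus the confusion counts they were computed from.
#'
#' @param pred Named predicted labels.
#' @param truth Named true labels over the same samples.
#' @return Tibble with one row per class: `class_name`, `tp`, `fn`, `tn`,
#'   `fp`, `sensitivity`, `specificity`, `f_score`.
#' @export
evaluate_predictions <- function(pred, truth) {
  ids <- names(truth)
  pred <- pred[ids]
  purrr::map_dfr(sort(unique(truth)), function(cl) {
    pos <- truth == cl; ppos <- pred == cl
    tp <- sum(pos & ppos); fn <- sum(pos & !ppos)
    tn <- sum(!pos & !ppos); fp <- sum(!pos & ppos)
    sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    tibble::tibble(class_name = cl, tp = tp, fn = fn, tn = tn, fp = fp,
                   sensitivity = sens, specificity = spec,
                   f_score = f_sens_spec(sens, spec))
  })
}

#' Robustness experiment runner
#'
#' Trains the rank-conservation (DIRAC), expression-value (GEV) and
#' within-sample-rank (GEV-rank) classifiers on a pristine training cohort
#' and evaluates each on the test cohort under a panel of perturbed
#' conditions: the six preprocessing variants V1-V6 applied to the raw test
#' data, a gene-wise batch shift on the test batch, and the same shift after
#' location-scale batch correction. Training data are always prepared with
#' V1 (log2).
#'
#' @param cfg A [sim_config()]; must assign a test batch
#'   (`test_fraction > 0`). The default scenario adds 10 planted
#'   differentially expressed genes that serve as the gene signature of the
#'   value-based baselines.
#' @param classifiers Subset of `c("DIRAC", "GEV", "GEV_Rank")`.
#' @param variants Preprocessing variants to evaluate, subset of
#'   `paste0("V", 1:6)` (may be empty).
#' @param batch_magnitude Standard deviation of the gene-wise batch shift on
#'   the log2 scale; `NULL` skips the batch conditions.
#' @param config An [svm_config()].
#' @param seed Master seed for generation, variant randomness and shift.
#' @return A tibble of class `dirac_report`: one row per
#'   (classifier, condition, class) with confusion counts, sensitivity,
#'   specificity and F-score. The generated dataset and trained models are
#'   attached as attributes `"dataset"` and `"models"`.
#' @export
run_robustness_suite <- function(cfg = sim_config(n_planted = 10),
                                 classifiers = c("DIRAC", "GEV", "GEV_Rank"),
                                 variants = paste0("V", 1:6),
                                 batch_magnitude = 4,
                                 config = svm_config(), seed = 1) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (cfg$test_fraction <= 0) {
    stop("`cfg` must allocate a test batch (test_fraction > 0)", call. = FALSE)
  }
  set.seed(seed)
  seeds <- sample.int(2147483646L, 4)
  ds <- generate_dataset(cfg, seed = seeds[1])
  m <- ds$expr
  train_ids <- sample_ids(m)[m$batches == "b1"]
  test_ids <- sample_ids(m)[m$batches == "b2"]
  raw_train <- subset_samples(m, train_ids)
  raw_test <- subset_samples(m, test_ids)
  log_train <- apply_preprocessing_variant(raw_train, "V1")
  log_test <- apply_preprocessing_variant(raw_test, "V1")
  gs <- ds$truth$gene_sets
  # gene signature for the value-based baselines: the planted differentially
  # expressed genes when the scenario has them (the analogue of a screened
  # gene signature), otherwise all discriminative genes
  sig_genes <- if (length(ds$truth$planted_genes)) ds$truth$planted_genes else
    ds$truth$discriminative_genes

  models <- list()
  if ("DIRAC" %in% classifiers)
    models$DIRAC <- train_dirac_classifier(log_train, gs, config = config)
  if ("GEV" %in% classifiers)
    models$GEV <- train_gev_classifier(log_train, sig_genes, config = config)
  if ("GEV_Rank" %in% classifiers)
    models$GEV_Rank <- train_gev_rank_classifier(log_train, sig_genes,
                                                 config = config)

  conditions <- list(baseline = log_test)
  for (vr in variants) {
    cond <- tryCatch(
      apply_preprocessing_variant(raw_test, vr, seed = seeds[2]),
      error = function(e) {
        message("condition ", vr, " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(cond)) conditions[[vr]] <- cond
  }
  if (!is.null(batch_magnitude)) {
    log_all <- apply_preprocessing_variant(m, "V1")
    shifted <- inject_batch_effect(log_all, mode = "gene_shift",
                                   magnitude = batch_magnitude,
                                   seed = seeds[3], reference = "b1")
    corrected <- simple_batch_correct(shifted)
    conditions$batch_present <- subset_samples(shifted, test_ids)
    conditions$batch_corrected <- subset_samples(corrected, test_ids)
  }

  truth <- m$labels[test_ids]
  report <- purrr::map_dfr(names(models), function(clf) {
    purrr::map_dfr(names(conditions), function(cond) {
      pred <- suppressMessages(stats::predict(models[[clf]], conditions[[cond]]))
      ev <- evaluate_predictions(pred, truth)
      tibble::tibble(classifier = clf, condition = cond, ev)
    })
  })
  class(report) <- c("dirac_report", class(report))
  attr(report, "dataset") <- ds
  attr(report, "models") <- models
  attr(report, "seed") <- seed
  report
}

#' Macro-averaged summary of a robustness report
#'
#' Convenience average of the per-class one-vs-rest metrics (the per-class
#' rows are the primary result).
#'
#' @param report A tibble from [run_robustness_suite()] or
#'   [evaluate_predictions()].
#' @return Tibble aggregated over classes.
#' @export
macro_average <- function(report) {
  grp <- intersect(c("classifier", "condition"), names(report))
  report |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(sensitivity = mean(.data$sensitivity),
                     specificity = mean(.data$specificity),
                     f_score = mean(.data$f_score), .groups = "drop")
}

#' Write a robustness report as tidy TSV plus a JSON manifest
#'
#' @param report A `dirac_report`.
#' @param path Output TSV path; the manifest is written next to it with a
#'   `.manifest.json` suffix.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(format = "diracnet-report", version = 1L,
                   seed = attr(report, "seed"),
                   conditions = unique(report$condition),
                   classifiers = unique(report$classifier))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @method autoplot dirac_report
#' @export
autoplot.dirac_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$class_name, y = .data$f_score,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$classifier)) +
    ggplot2::labs(x = "subtype", y = "F-score (harmonic mean of sens/spec)",
                  fill = "condition") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Bar-chart of per-class F-scores for one prediction
#'
#' @param ev A tibble from [evaluate_predictions()].
#' @return A ggplot object.
#' @export
plot_f_scores <- function(ev) {
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$class_name, y = .data$f_score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "subtype", y = "F-score") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
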