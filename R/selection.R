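#' Stratified two-way split of samples
#'
#' Splits sample IDs into two parts with per-class proportionality: each
#' class contributes `ceiling(n * fraction)` samples to part A (capped so
#' part B keeps at least one), drawn without replacement under the given
#' seed.
#'
#' @param sample_ids Character vector of sample IDs.
#' @param labels Named class labels covering `sample_ids`.
#' @param fraction Fraction allocated to part A, default 2/3.
#' @param seed Integer seed; the split is deterministic given it.
#' @return List with character vectors `part_a`, `part_b`.
#' @export
stratified_split <- function(sample_ids, labels, fraction = 2/3, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  lab <- labels[sample_ids]
  if (anyNA(lab)) stop("labels must cover every sample ID", call. = FALSE)
  counts <- table(lab)
  small <- names(which(counts < 3))
  if (length(small)) {
    stop("cannot stratify: class(es) with fewer than 3 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  part_a <- character()
  for (cl in sort(names(counts))) {
    ids <- sort(sample_ids[lab == cl])
    n_a <- min(ceiling(length(ids) * fraction), length(ids) - 1L)
    part_a <- c(part_a, sample(ids, n_a))
  }
  list(part_a = sample_ids[sample_ids %in% part_a],
       part_b = sample_ids[!sample_ids %in% part_a])
}

# Newton inversion of the trigamma function (for the moment estimator of the
# prior degrees of freedom).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated-t screen
#'
#' Two-group moderated t-statistics with gene-wise pooled variances shrunk
#' toward a common prior: the posterior variance is
#' `(d0 * s0^2 + df * s^2) / (d0 + df)`, with the prior `(d0, s0^2)`
#' estimated by the method of moments on the log pooled variances. Features
#' are returned ranked by decreasing `|t|` (ties broken by feature name).
#'
#' @param x Features x samples numeric matrix (or [dirac_expr]).
#' @param binary_labels Named two-level labels covering the columns of `x`.
#' @param top_k Number of top features to return (default 50; clamped with a
#'   warning when it exceeds the feature count).
#' @param prior_df `"moment"` (default) estimates the prior degrees of
#'   freedom; a numeric value overrides it (0 = no shrinkage, i.e. ordinary
#'   pooled t; `Inf` = complete shrinkage to `s0^2`).
#' @return Tibble with columns `feature`, `statistic`, `rank`, `top_k` rows.
#' @export
moderated_t_screen <- function(x, binary_labels, top_k = 50,
                               prior_df = "moment") {
  if (inherits(x, "dirac_expr")) x <- x$values
  lab <- binary_labels[colnames(x)]
  groups <- sort(unique(lab))
  if (length(groups) != 2) stop("binary labels required", call. = FALSE)
  i1 <- lab == groups[1]; i2 <- lab == groups[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group", call. = FALSE)
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1, var)
  v2 <- apply(x[, i2, drop = FALSE], 1, var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  if (all(s2 == 0)) stop("all features have zero variance", call. = FALSE)
  ok <- s2 > 0
  if (identical(prior_df, "moment")) {
    e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- if (sum(ok) > 1) sum((e - emean)^2) / (sum(ok) - 1) - trigamma(df / 2)
            else -1
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # all log-variances consistent with a single prior: infinite shrinkage
      d0 <- Inf
      s02 <- exp(emean)
      message("moment estimate of prior df non-finite; using complete shrinkage")
    }
  } else {
    d0 <- as.numeric(prior_df)
    s02 <- mean(s2[ok])
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
  tstat <- unname((m1 - m2) / sqrt(s2_post * (1 / n1 + 1 / n2)))
  out <- tibble::tibble(feature = rownames(x), statistic = tstat)
  out <- out[order(-abs(out$statistic), out$feature), ]
  if (top_k > nrow(out)) {
    warning("top_k (", top_k, ") exceeds feature count (", nrow(out),
            "); returning all features")
    top_k <- nrow(out)
  }
  out <- out[seq_len(top_k), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Single-feature global-test ranking
#'
#' Scores each (centered, scaled) feature by the squared covariance between
#' it and the 0/1 class indicator — the single-feature score statistic of
#' the global test — and ranks features from best to worst. Constant
#' features score 0 and rank last.
#'
#' @param x Samples x features numeric matrix.
#' @param binary_labels Named two-level labels covering the rows of `x`.
#' @return Tibble with `feature`, `score`, `rank`, ordered by decreasing
#'   score (ties broken by feature name).
#' @export
global_test_rank <- function(x, binary_labels) {
  lab <- binary_labels[rownames(x)]
  groups <- sort(unique(lab))
  if (length(groups) != 2) stop("binary labels required", call. = FALSE)
  y <- as.numeric(lab == groups[2])
  yc <- y - mean(y)
  sds <- apply(x, 2, sd)
  xs <- sweep(x, 2, colMeans(x))
  pos <- sds > 0
  xs[, pos] <- sweep(xs[, pos, drop = FALSE], 2, sds[pos], "/")
  xs[, !pos] <- 0
  q <- drop(crossprod(xs, yc))^2
  out <- tibble::tibble(feature = colnames(x), score = unname(q))
  out <- out[order(-out$score, out$feature), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Backward elimination over a fixed feature ranking
#'
#' Walks signature sizes from the full ranking down to 3, at each size
#' training a linear SVM on the top-`size` prefix and recording inner-test
#' sensitivity and specificity. The ranking is computed once; prefixes are
#' nested.
#'
#' @param x_train,x_test Samples x features matrices (train / inner test).
#' @param labels Named binary labels covering both sample sets.
#' @param ranking Character vector of feature names, best first.
#' @param positive_class Positive class label.
#' @param config An [svm_config()].
#' @return List with `trajectory` (tibble `size`, `sensitivity`,
#'   `specificity`), `best_size` (highest sensitivity, ties to the smaller
#'   size) and `best_features`.
#' @export
backward_elimination <- function(x_train, x_test, labels, ranking,
                                 positive_class, config = svm_config()) {
  if (length(ranking) < 3) stop("need at least 3 ranked features", call. = FALSE)
  if (!all(ranking %in% colnames(x_train))) {
    stop("ranking contains unknown features", call. = FALSE)
  }
  y_train <- labels[rownames(x_train)]
  y_test <- labels[rownames(x_test)]
  sizes <- seq(length(ranking), 3)
  traj <- purrr::map_dfr(sizes, function(k) {
    feats <- ranking[seq_len(k)]
    rule <- fit_linear_svm(x_train[, feats, drop = FALSE], y_train,
                           positive = positive_class, cost = config$cost)
    dec <- linear_decision(rule, x_test[, feats, drop = FALSE])
    pred <- ifelse(dec > 0, positive_class, "Rest")
    ss <- sensitivity_specificity(setNames(pred, rownames(x_test)),
                                  y_test, positive_class)
    tibble::tibble(size = k, sensitivity = ss[["sensitivity"]],
                   specificity = ss[["specificity"]])
  })
  best <- traj[order(-traj$sensitivity, traj$size), ]
  list(trajectory = traj, best_size = best$size[1],
       best_features = ranking[seq_len(best$size[1])])
}

# Feature construction shared by the inner and outer loops: either raw gene
# expression (genes as features) or per-set rank-difference scores computed
# from templates estimated on the training subset only.
selection_features <- function(m, gs, binlab, train_ids, positive_class) {
  if (is.null(gs)) {
    t(m$values)
  } else {
    build_rds_features(m, gs, positive_class, labels = binlab,
                       train_ids = train_ids)$features
  }
}

#' Double-loop cross-validated signature selection
#'
#' Selects a subtype-specific feature signature on a discovery cohort via
#' nested cross-validation: each outer (OCV) iteration splits the discovery
#' samples 2/3-1/3 into training/test; each inner (ICV) iteration re-splits
#' the training set 2/3-1/3, screens the top `top_k` features with the
#' moderated-t statistic on the inner-training set, ranks them with the
#' single-feature global test, and backward-eliminates down to 3 while
#' recording inner-test sensitivity. ICV trajectories are aggregated per
#' size (mean by default, median as the alternative reading) and the best
#' size (ties to the smaller) is re-fit on the full training set to give the
#' OCV iteration's list; the final signature is the OCV list with the
#' highest outer-test sensitivity (ties resolved by the median-size list).
#'
#' With `gs = NULL` features are genes; with a gene-set collection they are
#' per-set rank-difference scores whose templates are re-estimated from each
#' training subset (no information leaks from any test partition).
#'
#' @param m A [dirac_expr] restricted to the discovery cohort.
#' @param gs Optional [geneset_collection] (rank-conservation pipeline);
#'   `NULL` for the expression pipeline.
#' @param class_name Positive class to discriminate from the pooled rest.
#' @param labels Named class labels (defaults to `m$labels`).
#' @param n_ocv,n_icv Numbers of outer / inner iterations (defaults 100).
#' @param fraction Training fraction of each split, default 2/3.
#' @param top_k Screen size, default 50.
#' @param config An [svm_config()].
#' @param seed Master seed; all internal seeds derive from it.
#' @param icv_aggregate `"mean"` (default) or `"median"` aggregation of
#'   inner-test sensitivities across ICV iterations.
#' @param max_retries Resampling attempts when an inner split degenerates.
#' @return An object of class `signature_list`: `class_name`, `features`,
#'   `size`, `mean_sensitivity` (inner aggregate at the chosen size),
#'   `test_sensitivity` (outer), and `provenance` (seeds, splits, chosen
#'   sizes, trajectories).
#' @export
nested_cv_select <- function(m, gs = NULL, class_name, labels = NULL,
                             n_ocv = 100, n_icv = 100, fraction = 2/3,
                             top_k = 50, config = svm_config(), seed = 1,
                             icv_aggregate = c("mean", "median"),
                             max_retries = 10) {
  m <- as_dirac_expr(m)
  icv_aggregate <- match.arg(icv_aggregate)
  lab <- require_labels(m, labels)
  if (!class_name %in% lab) stop("class '", class_name, "' absent", call. = FALSE)
  binlab <- setNames(ifelse(lab == class_name, class_name, "Rest"), names(lab))
  ids <- sample_ids(m)
  set.seed(seed)
  ocv_seeds <- sample.int(2147483646L, n_ocv)
  icv_seed_pool <- matrix(sample.int(2147483646L, n_ocv * n_icv * (max_retries + 1)),
                          nrow = n_ocv)
  ocv_results <- vector("list", n_ocv)
  for (i in seq_len(n_ocv)) {
    sp <- stratified_split(ids, binlab, fraction, seed = ocv_seeds[i])
    tr <- sp$part_a; te <- sp$part_b
    trajectories <- vector("list", n_icv)
    used_seeds <- integer(n_icv)
    pool <- icv_seed_pool[i, ]
    pool_pos <- 1L
    for (j in seq_len(n_icv)) {
      done <- FALSE
      for (attempt in seq_len(max_retries + 1)) {
        sj <- pool[pool_pos]; pool_pos <- pool_pos + 1L
        res <- tryCatch({
          isp <- stratified_split(tr, binlab, fraction, seed = sj)
          feats <- selection_features(subset_samples(m, c(isp$part_a, isp$part_b)),
                                      gs, binlab, isp$part_a, class_name)
          screened <- moderated_t_screen(t(feats[isp$part_a, , drop = FALSE]),
                                         binlab, top_k = min(top_k, ncol(feats)))
          ranking <- global_test_rank(
            feats[isp$part_a, screened$feature, drop = FALSE], binlab)
          backward_elimination(feats[isp$part_a, , drop = FALSE],
                               feats[isp$part_b, , drop = FALSE],
                               binlab, ranking$feature, class_name, config)
        }, error = function(e) e)
        if (!inherits(res, "error")) {
          trajectories[[j]] <- res$trajectory
          used_seeds[j] <- sj
          done <- TRUE
          break
        }
      }
      if (!done) {
        stop("ICV iteration ", j, " of OCV ", i, " failed after ",
             max_retries, " retries: ", conditionMessage(res), call. = FALSE)
      }
    }
    agg <- dplyr::bind_rows(trajectories) |>
      dplyr::group_by(.data$size) |>
      dplyr::summarise(sens = if (icv_aggregate == "mean")
        mean(.data$sensitivity) else median(.data$sensitivity),
        .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$sens), .data$size)
    best_size <- agg$size[1]
    # refit screen + ranking on the full training set, take the top prefix
    feats_tr <- selection_features(m, gs, binlab, tr, class_name)
    screened <- moderated_t_screen(t(feats_tr[tr, , drop = FALSE]), binlab,
                                   top_k = min(top_k, ncol(feats_tr)))
    ranking <- global_test_rank(feats_tr[tr, screened$feature, drop = FALSE],
                                binlab)
    sig <- ranking$feature[seq_len(best_size)]
    rule <- fit_linear_svm(feats_tr[tr, sig, drop = FALSE], binlab[tr],
                           positive = class_name, cost = config$cost)
    dec <- linear_decision(rule, feats_tr[te, sig, drop = FALSE])
    pred <- setNames(ifelse(dec > 0, class_name, "Rest"), te)
    ss <- sensitivity_specificity(pred, binlab[te], class_name)
    ocv_results[[i]] <- list(seed = ocv_seeds[i], icv_seeds = used_seeds,
                             train_ids = tr, test_ids = te,
                             chosen_size = best_size, features = sig,
                             inner_sensitivity = agg$sens[1],
                             test_sensitivity = ss[["sensitivity"]],
                             test_specificity = ss[["specificity"]],
                             trajectory = agg)
  }
  test_sens <- vapply(ocv_results, `[[`, 0, "test_sensitivity")
  winners <- which(test_sens == max(test_sens))
  if (length(winners) > 1) {
    sizes <- vapply(ocv_results[winners], `[[`, 0L, "chosen_size")
    keys <- vapply(ocv_results[winners], function(r) paste(r$features, collapse = ","), "")
    ord <- order(sizes, keys)
    winners <- winners[ord][ceiling(length(winners) / 2)]
  }
  win <- ocv_results[[winners[1]]]
  structure(list(class_name = class_name, features = win$features,
                 size = win$chosen_size,
                 mean_sensitivity = win$inner_sensitivity,
                 test_sensitivity = win$test_sensitivity,
                 provenance = list(seed = seed, n_ocv = n_ocv, n_icv = n_icv,
                                   fraction = fraction, top_k = top_k,
                                   icv_aggregate = icv_aggregate,
                                   pipeline = if (is.null(gs)) "expression" else "rank-conservation",
                                   discovery_ids = ids,
                                   winning_iteration = winners[1],
                                   ocv = ocv_results)),
            class = "signature_list")
}

#' @export
print.signature_list <- function(x, ...) {
  cat("<signature_list> class '", x$class_name, "': ", x$size,
      " feature(s), inner sensitivity ", round(x$mean_sensitivity, 3),
      ", outer-test sensitivity ", round(x$test_sensitivity, 3), "\n",
      sep = "")
  cat("  ", paste(x$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy signature_list
#' @export
tidy.signature_list <- function(x, ...) {
  tibble::tibble(class_name = x$class_name, feature = x$features,
                 rank = seq_along(x$features))
}

#' @method glance signature_list
#' @export
glance.signature_list <- function(x, ...) {
  tibble::tibble(class_name = x$class_name, size = x$size,
                 mean_sensitivity = x$mean_sensitivity,
                 test_sensitivity = x$test_sensitivity)
}

#' Serialize / restore a signature list as JSON
#'
#' The document records the selected features together with the full audit
#' trail (seeds, split IDs, per-size trajectories).
#'
#' @param sig A [nested_cv_select()] result.
#' @param path File path.
#' @return `write_signature` returns `path` invisibly; `read_signature` the
#'   signature list.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "signature_list"))
  doc <- unclass(sig)
  doc$provenance$ocv <- lapply(doc$provenance$ocv, function(r) {
    r$trajectory <- as.list(r$trajectory)
    r
  })
  jsonlite::write_json(list(format = "diracnet-signature", version = 1L,
                            signature = doc),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "diracnet-signature")) {
    stop("not a diracnet signature file: ", path, call. = FALSE)
  }
  structure(doc$signature, class = "signature_list")
}

#' Discovery/validation split plus signature selection and validation
#'
#' Convenience wrapper for the full published workflow: split the cohort
#' 2/3-1/3 (stratified) into discovery and validation, run
#' [nested_cv_select()] on the discovery partition, train the final
#' one-vs-rest SVM on the full discovery set with the selected signature,
#' and report validation sensitivity/specificity/F-score. Validation samples
#' never enter screening, ranking, elimination or template estimation.
#'
#' @inheritParams nested_cv_select
#' @param ... Passed on to [nested_cv_select()].
#' @return List with `signature` (the [nested_cv_select()] result, its
#'   provenance extended with `validation_ids`), `validation` (one-row
#'   tibble of metrics) and `predictions`.
#' @export
select_and_validate <- function(m, gs = NULL, class_name, labels = NULL,
                                fraction = 2/3, config = svm_config(),
                                seed = 1, ...) {
  m <- as_dirac_expr(m)
  lab <- require_labels(m, labels)
  binlab <- setNames(ifelse(lab == class_name, class_name, "Rest"), names(lab))
  set.seed(seed)
  seeds <- sample.int(2147483646L, 2)
  sp <- stratified_split(sample_ids(m), binlab, fraction, seed = seeds[1])
  disc <- subset_samples(m, sp$part_a)
  sig <- nested_cv_select(disc, gs = gs, class_name = class_name,
                          labels = binlab[sp$part_a], fraction = fraction,
                          config = config, seed = seeds[2], ...)
  sig$provenance$validation_ids <- sp$part_b
  feats <- selection_features(m, gs, binlab, sp$part_a, class_name)
  rule <- fit_linear_svm(feats[sp$part_a, sig$features, drop = FALSE],
                         binlab[sp$part_a], positive = class_name,
                         cost = config$cost)
  dec <- linear_decision(rule, feats[sp$part_b, sig$features, drop = FALSE])
  pred <- setNames(ifelse(dec > 0, class_name, "Rest"), sp$part_b)
  ss <- sensitivity_specificity(pred, binlab[sp$part_b], class_name)
  list(signature = sig,
       validation = tibble::tibble(class_name = class_name,
                                   sensitivity = ss[["sensitivity"]],
                                   specificity = ss[["specificity"]],
                                   f_score = f_sens_spec(ss[["sensitivity"]],
                                                         ss[["specificity"]])),
       predictions = pred)
}
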