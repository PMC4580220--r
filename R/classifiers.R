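#' SVM configuration
#'
#' The classifiers use linear-kernel support vector machines so the learned
#' weights remain interpretable per feature.
#'
#' @param cost Soft-margin cost C, default 1.
#' @return A list with class `svm_config`.
#' @export
svm_config <- function(cost = 1) {
  stopifnot(is.numeric(cost), cost > 0)
  structure(list(cost = cost), class = "svm_config")
}

# Fit a linear SVM and extract an explicit linear decision rule
# decision(x) = x %*% weights + bias, positive => `positive` level.
# e1071's sign convention depends on factor-level order, so the orientation
# is verified against the fitted decision values.
fit_linear_svm <- function(x, y, positive, cost = 1) {
  y <- factor(y, levels = c(positive, setdiff(unique(y), positive)))
  if (nlevels(y) != 2) stop("binary SVM needs exactly two label values", call. = FALSE)
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  d0 <- drop(x %*% w) - fit$rho
  dv <- drop(attr(stats::predict(fit, x, decision.values = TRUE), "decision.values"))
  flip <- if (sum(abs(d0 - dv)) <= sum(abs(d0 + dv))) 1 else -1
  pos_first <- startsWith(colnames(attr(stats::predict(fit, x, decision.values = TRUE),
                                        "decision.values")), paste0(positive, "/"))
  sgn <- if (pos_first) flip else -flip
  list(weights = setNames(sgn * w, colnames(x)), bias = -sgn * fit$rho,
       cost = cost, positive = positive)
}

linear_decision <- function(rule, x) {
  drop(x[, names(rule$weights), drop = FALSE] %*% rule$weights) + rule$bias
}

#' Rank-difference-score feature matrix for a one-vs-rest problem
#'
#' For each retained gene set, the feature is the sample's RMS under the
#' positive class's template minus its RMS under the pooled-Rest template.
#' Templates are estimated from training samples only.
#'
#' @param m A [dirac_expr] providing the samples to score.
#' @param gs A coverage-filtered [geneset_collection].
#' @param positive_class Positive class name.
#' @param labels Named training labels (defaults to `m$labels`).
#' @param train_ids Sample IDs used for template estimation (defaults to all
#'   labelled samples of `m`).
#' @return A list: `features` (samples x sets matrix in \[-1, 1\]),
#'   `templates_pos`, `templates_rest` (named by set).
#' @export
build_rds_features <- function(m, gs, positive_class, labels = NULL,
                               train_ids = NULL) {
  m <- as_dirac_expr(m)
  lab <- require_labels(m, labels)
  if (is.null(train_ids)) train_ids <- names(lab)
  pos_ids <- train_ids[lab[train_ids] == positive_class]
  rest_ids <- train_ids[lab[train_ids] != positive_class]
  if (!length(pos_ids)) stop("positive class '", positive_class, "' empty", call. = FALSE)
  if (!length(rest_ids)) stop("Rest is empty for '", positive_class, "'", call. = FALSE)
  sets <- sort(names(gs))
  t_pos <- t_rest <- list()
  feats <- matrix(0, ncol(m$values), length(sets),
                  dimnames = list(sample_ids(m), sets))
  for (s in sets) {
    t_pos[[s]] <- build_rank_template(m, gs[[s]], pos_ids, s, positive_class)
    t_rest[[s]] <- build_rank_template(m, gs[[s]], rest_ids, s, "Rest")
    b <- pair_bits(m$values, t_pos[[s]]$pairs)
    feats[, s] <- rms_columns(b, t_pos[[s]]) - rms_columns(b, t_rest[[s]])
  }
  list(features = feats, templates_pos = t_pos, templates_rest = t_rest)
}

rds_from_templates <- function(values, t_pos, t_rest) {
  sets <- names(t_pos)
  feats <- matrix(0, ncol(values), length(sets),
                  dimnames = list(colnames(values), sets))
  for (s in sets) {
    b <- pair_bits(values, t_pos[[s]]$pairs)
    feats[, s] <- rms_columns(b, t_pos[[s]]) - rms_columns(b, t_rest[[s]])
  }
  feats
}

#' Train the multi-network rank-conservation classifier
#'
#' One-vs-rest scheme: for every class, class and pooled-Rest rank templates
#' are estimated per gene set, rank-difference-score features are built, and
#' a linear SVM is fitted on them. RDS features are already bounded in
#' \[-1, 1\] and are not re-standardized. A two-class problem yields a single
#' binary sub-model.
#'
#' @param m A [dirac_expr] of training samples.
#' @param gs A coverage-filtered [geneset_collection].
#' @param labels Named class labels (defaults to `m$labels`).
#' @param config An [svm_config()].
#' @return An object of class `dirac_classifier`.
#' @export
train_dirac_classifier <- function(m, gs, labels = NULL, config = svm_config()) {
  m <- as_dirac_expr(m)
  lab <- require_labels(m, labels)
  classes <- sort(unique(lab))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  small <- names(which(table(lab) < 2))
  if (length(small)) {
    stop("class(es) with fewer than 2 training samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  model_classes <- if (length(classes) == 2) classes[1] else classes
  sub <- lapply(model_classes, function(cl) {
    rds <- build_rds_features(m, gs, cl, lab)
    y <- ifelse(lab[rownames(rds$features)] == cl, cl, "Rest")
    rule <- fit_linear_svm(rds$features, y, positive = cl, cost = config$cost)
    list(class_name = cl, templates_pos = rds$templates_pos,
         templates_rest = rds$templates_rest, rule = rule)
  })
  names(sub) <- model_classes
  structure(list(type = "dirac", classes = classes, sets = sort(names(gs)),
                 gene_sets = gs[sort(names(gs))], sub_models = sub,
                 config = config),
            class = c("dirac_classifier", "diracnet_model"))
}

#' @export
print.dirac_classifier <- function(x, ...) {
  cat("<dirac_classifier> ", length(x$classes), " classes (",
      paste(x$classes, collapse = ", "), "), ", length(x$sets),
      " gene-set features, linear SVM cost ", x$config$cost, "\n", sep = "")
  invisible(x)
}

#' Predict classes with a trained model
#'
#' Decision values of every one-vs-rest sub-model are computed from the
#' stored templates/weights and the sample is assigned the argmax class;
#' exact ties go to the lexicographically first class (with a message).
#' Predictions are invariant to per-sample strictly increasing transforms of
#' the expression values.
#'
#' @param object A trained `dirac_classifier`.
#' @param newdata A [dirac_expr] or genes x samples matrix containing every
#'   gene of the model's sets.
#' @param ... Unused.
#' @return Named character vector of predicted classes.
#' @export
predict.dirac_classifier <- function(object, newdata, ...) {
  v <- if (inherits(newdata, "dirac_expr")) newdata$values else newdata
  for (s in object$sets) {
    missing <- setdiff(object$gene_sets[[s]], rownames(v))
    if (length(missing)) {
      stop("set '", s, "': gene(s) missing from new data: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  dec <- vapply(object$sub_models, function(sm) {
    feats <- rds_from_templates(v, sm$templates_pos, sm$templates_rest)
    linear_decision(sm$rule, feats)
  }, numeric(ncol(v)))
  dec <- matrix(dec, nrow = ncol(v),
                dimnames = list(colnames(v), names(object$sub_models)))
  decide_from_decision_values(dec, object$classes)
}

# shared argmax-with-tie-logging rule; for a 2-class model the single
# sub-model's sign decides between the two classes.
decide_from_decision_values <- function(dec, classes) {
  if (ncol(dec) == 1 && length(classes) == 2) {
    pred <- ifelse(dec[, 1] > 0, colnames(dec)[1], setdiff(classes, colnames(dec)[1]))
    ties <- dec[, 1] == 0
    if (any(ties)) {
      message(sum(ties), " decision tie(s) broken toward '", sort(classes)[1], "'")
      pred[ties] <- sort(classes)[1]
    }
    return(setNames(pred, rownames(dec)))
  }
  pred <- apply(dec, 1, function(d) {
    top <- colnames(dec)[d == max(d)]
    sort(top)[1]
  })
  n_tie <- sum(apply(dec, 1, function(d) sum(d == max(d)) > 1))
  if (n_tie) message(n_tie, " decision tie(s) broken lexicographically")
  setNames(pred, rownames(dec))
}

# standardized expression features on a fixed gene panel; constant genes
# (sd 0) are dropped with a warning and recorded on the model.
standardize_features <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
  }
  keep <- scale > 0
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(head(names(which(!keep)), 5), collapse = ", "))
  }
  list(x = sweep(sweep(x[, keep, drop = FALSE], 2, center[keep]), 2,
                 scale[keep], "/"),
       center = center[keep], scale = scale[keep])
}

train_value_classifier <- function(m, signature_genes, labels, config, rank_based) {
  m <- as_dirac_expr(m)
  lab <- require_labels(m, labels)
  classes <- sort(unique(lab))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  missing <- setdiff(signature_genes, gene_ids(m))
  if (length(missing)) {
    stop("signature gene(s) missing: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  universe <- gene_ids(m)
  v <- if (rank_based) apply(m$values, 2, rank) else m$values
  x <- t(v[signature_genes, , drop = FALSE])
  std <- standardize_features(x)
  model_classes <- if (length(classes) == 2) classes[1] else classes
  sub <- lapply(model_classes, function(cl) {
    y <- ifelse(lab[rownames(std$x)] == cl, cl, "Rest")
    list(class_name = cl,
         rule = fit_linear_svm(std$x, y, positive = cl, cost = config$cost))
  })
  names(sub) <- model_classes
  structure(list(type = if (rank_based) "gev_rank" else "gev",
                 classes = classes, signature_genes = signature_genes,
                 universe = if (rank_based) universe else NULL,
                 center = std$center, scale = std$scale,
                 sub_models = sub, config = config),
            class = c("gev_classifier", "diracnet_model"))
}

#' Train the expression-value (GEV) baseline classifier
#'
#' One-vs-rest linear SVM on the raw expression of a gene signature,
#' standardized by training-set mean and standard deviation (stored and
#' re-applied at prediction time). Unlike the rank-based models, its
#' predictions are sensitive to per-sample monotone transforms and to
#' gene-wise batch shifts.
#'
#' @param m A [dirac_expr] of training samples.
#' @param signature_genes Genes used as features.
#' @param labels Named class labels (defaults to `m$labels`).
#' @param config An [svm_config()].
#' @return An object of class `gev_classifier`.
#' @export
train_gev_classifier <- function(m, signature_genes, labels = NULL,
                                 config = svm_config()) {
  train_value_classifier(m, signature_genes, labels, config, rank_based = FALSE)
}

#' Train the within-sample-rank (GEV-rank) baseline classifier
#'
#' Each sample's values are replaced by within-sample ranks (average rank on
#' ties) over the full gene universe before subsetting to the signature;
#' the rest of the pipeline is identical to [train_gev_classifier()]. On
#' tie-free data this makes the features invariant to per-sample strictly
#' increasing transforms.
#'
#' @inheritParams train_gev_classifier
#' @return An object of class `gev_classifier` with `type = "gev_rank"`.
#' @export
train_gev_rank_classifier <- function(m, signature_genes, labels = NULL,
                                      config = svm_config()) {
  train_value_classifier(m, signature_genes, labels, config, rank_based = TRUE)
}

#' @export
print.gev_classifier <- function(x, ...) {
  cat("<gev_classifier> type '", x$type, "', ", length(x$classes),
      " classes, ", length(x$signature_genes), " signature genes\n", sep = "")
  invisible(x)
}

#' @rdname predict.dirac_classifier
#' @export
predict.gev_classifier <- function(object, newdata, ...) {
  v <- if (inherits(newdata, "dirac_expr")) newdata$values else newdata
  if (identical(object$type, "gev_rank")) {
    missing <- setdiff(object$universe, rownames(v))
    if (length(missing)) {
      stop("rank universe gene(s) missing from new data: ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
    }
    v <- apply(v[object$universe, , drop = FALSE], 2, rank)
  }
  missing <- setdiff(names(object$center), rownames(v))
  if (length(missing)) {
    stop("signature gene(s) missing from new data: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- t(v[names(object$center), , drop = FALSE])
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  dec <- vapply(object$sub_models, function(sm) linear_decision(sm$rule, x),
                numeric(nrow(x)))
  dec <- matrix(dec, nrow = nrow(x),
                dimnames = list(rownames(x), names(object$sub_models)))
  decide_from_decision_values(dec, object$classes)
}

#' Per-sample decision values of a fitted model
#'
#' @param object A `dirac_classifier` or `gev_classifier`.
#' @param newdata Expression data as in [predict.dirac_classifier()].
#' @return Samples x sub-models matrix of linear decision values.
#' @export
decision_values <- function(object, newdata) {
  v <- if (inherits(newdata, "dirac_expr")) newdata$values else newdata
  if (inherits(object, "dirac_classifier")) {
    dec <- vapply(object$sub_models, function(sm) {
      feats <- rds_from_templates(v, sm$templates_pos, sm$templates_rest)
      linear_decision(sm$rule, feats)
    }, numeric(ncol(v)))
  } else {
    if (identical(object$type, "gev_rank")) {
      v <- apply(v[object$universe, , drop = FALSE], 2, rank)
    }
    x <- t(v[names(object$center), , drop = FALSE])
    x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
    dec <- vapply(object$sub_models, function(sm) linear_decision(sm$rule, x),
                  numeric(nrow(x)))
  }
  matrix(dec, ncol = length(object$sub_models),
         dimnames = list(colnames(v), names(object$sub_models)))
}

#' @method tidy dirac_classifier
#' @export
tidy.dirac_classifier <- function(x, ...) {
  purrr::map_dfr(x$sub_models, function(sm) {
    tibble::tibble(class_name = sm$class_name,
                   feature = names(sm$rule$weights),
                   weight = unname(sm$rule$weights))
  })
}

#' @method tidy gev_classifier
#' @export
tidy.gev_classifier <- function(x, ...) tidy.dirac_classifier(x, ...)

#' @method glance dirac_classifier
#' @export
glance.dirac_classifier <- function(x, ...) {
  tibble::tibble(type = x$type, n_classes = length(x$classes),
                 n_features = length(x$sets), cost = x$config$cost)
}

#' @method glance gev_classifier
#' @export
glance.gev_classifier <- function(x, ...) {
  tibble::tibble(type = x$type, n_classes = length(x$classes),
                 n_features = length(x$signature_genes), cost = x$config$cost)
}
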