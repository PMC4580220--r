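#' Save or load a trained classifier as versioned JSON
#'
#' The representation stores everything prediction needs (gene sets, rank
#' templates, standardization constants, linear SVM weights), so a restored
#' model produces bit-identical predictions on the same data.
#'
#' @param model A `dirac_classifier` or `gev_classifier`.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "diracnet_model"))
  doc <- list(format = "diracnet-model", version = 1L, type = model$type,
              classes = model$classes, cost = model$config$cost)
  if (inherits(model, "dirac_classifier")) {
    doc$gene_sets <- model$gene_sets
    doc$sub_models <- lapply(model$sub_models, function(sm) {
      list(class_name = sm$class_name,
           templates_pos = lapply(sm$templates_pos, serialize_template),
           templates_rest = lapply(sm$templates_rest, serialize_template),
           weights = as.list(sm$rule$weights), bias = sm$rule$bias)
    })
  } else {
    doc$signature_genes <- model$signature_genes
    doc$universe <- model$universe
    doc$center <- as.list(model$center)
    doc$scale <- as.list(model$scale)
    doc$sub_models <- lapply(model$sub_models, function(sm) {
      list(class_name = sm$class_name,
           weights = as.list(sm$rule$weights), bias = sm$rule$bias)
    })
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

serialize_template <- function(rt) {
  list(set_name = rt$set_name, class_name = rt$class_name,
       genes = rt$pairs$genes, probabilities = unname(rt$probabilities),
       bits = rt$bits)
}

deserialize_template <- function(t) {
  pairs <- gene_pairs(unlist(t$genes))
  structure(list(set_name = t$set_name, class_name = t$class_name,
                 pairs = pairs,
                 probabilities = setNames(as.numeric(unlist(t$probabilities)),
                                          pairs$labels),
                 bits = as.integer(unlist(t$bits))),
            class = "rank_template")
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "diracnet-model")) {
    stop("not a diracnet model file: ", path, call. = FALSE)
  }
  classes <- unlist(doc$classes)
  config <- svm_config(cost = doc$cost)
  if (identical(doc$type, "dirac")) {
    gs <- geneset_collection(lapply(doc$gene_sets, unlist))
    sub <- lapply(doc$sub_models, function(sm) {
      list(class_name = sm$class_name,
           templates_pos = lapply(sm$templates_pos, deserialize_template),
           templates_rest = lapply(sm$templates_rest, deserialize_template),
           rule = list(weights = unlist(sm$weights), bias = sm$bias,
                       cost = doc$cost, positive = sm$class_name))
    })
    names(sub) <- names(doc$sub_models)
    structure(list(type = "dirac", classes = classes, sets = sort(names(gs)),
                   gene_sets = gs[sort(names(gs))], sub_models = sub,
                   config = config),
              class = c("dirac_classifier", "diracnet_model"))
  } else {
    sub <- lapply(doc$sub_models, function(sm) {
      list(class_name = sm$class_name,
           rule = list(weights = unlist(sm$weights), bias = sm$bias,
                       cost = doc$cost, positive = sm$class_name))
    })
    names(sub) <- names(doc$sub_models)
    structure(list(type = doc$type, classes = classes,
                   signature_genes = unlist(doc$signature_genes),
                   universe = if (!is.null(doc$universe)) unlist(doc$universe),
                   center = unlist(doc$center), scale = unlist(doc$scale),
                   sub_models = sub, config = config),
              class = c("gev_classifier", "diracnet_model"))
  }
}
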