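#' Expression set container
#'
#' A light container for a genes x samples expression matrix together with
#' optional per-sample class labels and batch labels. Values may be on any
#' positive or log scale; rank-based operations are invariant to the choice.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique rownames (gene IDs) and colnames (sample IDs). No missing values
#'   are allowed: pairwise comparisons are undefined on missing data.
#' @param labels Optional named character vector of class labels, names being
#'   sample IDs covering all columns of `values`.
#' @param batches Optional named character vector of batch labels, same naming
#'   convention as `labels`.
#'
#' @return An object of class `dirac_expr`: a list with elements `values`,
#'   `labels`, `batches`.
#' @export
#'
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' e <- dirac_expr(x, labels = setNames(rep(c("A", "B"), 2), colnames(x)))
#' e
dirac_expr <- function(values, labels = NULL, batches = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene IDs in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs in expression matrix", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("missing values in expression matrix; impute or filter upstream",
         call. = FALSE)
  }
  labels  <- check_sample_annotation(labels, colnames(values), "labels")
  batches <- check_sample_annotation(batches, colnames(values), "batches")
  structure(list(values = values, labels = labels, batches = batches),
            class = "dirac_expr")
}

check_sample_annotation <- function(ann, sample_ids, what) {
  if (is.null(ann)) return(NULL)
  ann <- ann[sample_ids]
  if (anyNA(ann) || anyNA(names(ann))) {
    stop("`", what, "` must cover every sample ID", call. = FALSE)
  }
  as.character(ann) |> setNames(sample_ids)
}

#' @export
print.dirac_expr <- function(x, ...) {
  cat("<dirac_expr> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  classes: ", paste0(names(tab), " (", tab, ")", collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$batches)) {
    tab <- table(x$batches)
    cat("  batches: ", paste0(names(tab), " (", tab, ")", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.dirac_expr <- function(x) dim(x$values)

#' Gene and sample identifiers
#'
#' @param x A [dirac_expr] object.
#' @return Character vector of gene IDs / sample IDs.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression set by sample IDs
#'
#' @param x A [dirac_expr] object.
#' @param samples Character vector of sample IDs to keep (order preserved).
#' @return A [dirac_expr] with the selected columns and matching annotation.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "dirac_expr"))
  missing <- setdiff(samples, sample_ids(x))
  if (length(missing)) {
    stop("unknown sample IDs: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  dirac_expr(x$values[, samples, drop = FALSE],
             labels  = x$labels[samples],
             batches = x$batches[samples])
}

# coerce a matrix-or-dirac_expr argument to dirac_expr
as_dirac_expr <- function(m, labels = NULL, batches = NULL) {
  if (inherits(m, "dirac_expr")) {
    if (!is.null(labels))  m$labels  <- check_sample_annotation(labels, sample_ids(m), "labels")
    if (!is.null(batches)) m$batches <- check_sample_annotation(batches, sample_ids(m), "batches")
    return(m)
  }
  dirac_expr(m, labels = labels, batches = batches)
}

# labels required by several operations
require_labels <- function(m, labels = NULL) {
  lab <- if (is.null(labels)) m$labels else
    check_sample_annotation(labels, sample_ids(m), "labels")
  if (is.null(lab)) stop("class labels are required", call. = FALSE)
  lab
}
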