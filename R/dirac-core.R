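#' Canonical gene-pair index for a gene set
#'
#' Pairs (i, j) with i < j under lexicographic gene order, enumerated
#' row-major — the fixed indexing shared by comparison vectors, templates
#' and scores.
#'
#' @param genes Character vector of gene IDs (sorted internally).
#' @return A list with `genes` (sorted), integer vectors `i`, `j`, and
#'   `labels` of the form `"gA<gB"`.
#' @export
gene_pairs <- function(genes) {
  genes <- sort(unique(as.character(genes)))
  k <- length(genes)
  if (k < 2) stop("need at least 2 genes to form pairs", call. = FALSE)
  idx <- combn(k, 2)
  list(genes = genes, i = idx[1, ], j = idx[2, ],
       labels = paste0(genes[idx[1, ]], "<", genes[idx[2, ]]))
}

# pairwise comparison bits for a genes x samples matrix restricted to a set.
# Rows follow the pair index; bit = 1 iff value(g_i) < value(g_j) strictly
# (ties give 0).
pair_bits <- function(values, pairs) {
  x <- values[pairs$genes, , drop = FALSE]
  if (anyNA(x) || any(!is.finite(x))) {
    stop("non-finite expression values in pair comparison", call. = FALSE)
  }
  b <- (x[pairs$i, , drop = FALSE] < x[pairs$j, , drop = FALSE]) * 1L
  rownames(b) <- pairs$labels
  b
}

#' Pairwise comparison vector of one sample
#'
#' Binarizes the within-sample ordering of a gene set: bit ij is 1 iff the
#' sample expresses gene i strictly below gene j. The vector is unchanged by
#' any strictly increasing transform of the sample's values.
#'
#' @param sample_values Named numeric vector of expression values covering
#'   the set's genes.
#' @param pairs A pair index from [gene_pairs()].
#' @return Object of class `pair_comparison`: list with `pairs` and integer
#'   `bits`.
#' @export
#'
#' @examples
#' p <- gene_pairs(c("g1", "g2", "g3"))
#' pair_comparison_vector(c(g1 = 1, g2 = 2, g3 = 3), p)$bits
pair_comparison_vector <- function(sample_values, pairs) {
  x <- matrix(sample_values[pairs$genes], ncol = 1,
              dimnames = list(pairs$genes, "s"))
  structure(list(pairs = pairs, bits = drop(pair_bits(x, pairs))),
            class = "pair_comparison")
}

#' Estimate a class Rank Template
#'
#' For every gene pair, the empirical probability that gene i is expressed
#' below gene j across the class's samples; the template bit is 1 iff that
#' probability strictly exceeds 0.5 (a probability of exactly 0.5 yields 0).
#'
#' @param m A [dirac_expr] or genes x samples matrix.
#' @param set_genes Genes of the set (must be measured in `m`).
#' @param class_samples Sample IDs of the class (at least one).
#' @param set_name,class_name Identifiers stored on the template.
#' @return Object of class `rank_template`: list with `set_name`,
#'   `class_name`, `pairs`, numeric `probabilities` and integer `bits`.
#' @export
build_rank_template <- function(m, set_genes, class_samples,
                                set_name = "set", class_name = "class") {
  v <- if (inherits(m, "dirac_expr")) m$values else m
  if (!length(class_samples)) stop("empty class: no samples to estimate a template", call. = FALSE)
  missing <- setdiff(set_genes, rownames(v))
  if (length(missing)) {
    stop("set '", set_name, "' genes missing from data: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  pairs <- gene_pairs(set_genes)
  b <- pair_bits(v[, class_samples, drop = FALSE], pairs)
  p <- rowMeans(b)
  structure(list(set_name = set_name, class_name = class_name, pairs = pairs,
                 probabilities = p, bits = as.integer(p > 0.5)),
            class = "rank_template")
}

#' @export
print.rank_template <- function(x, ...) {
  cat("<rank_template> set '", x$set_name, "', class '", x$class_name,
      "': ", length(x$bits), " pairs over ", length(x$pairs$genes),
      " genes\n", sep = "")
  invisible(x)
}

check_same_pairs <- function(a, b) {
  if (!identical(a$labels, b$labels)) {
    stop("pair indices differ; comparison vector and template must be built ",
         "on the same canonical gene order", call. = FALSE)
  }
}

#' Rank Matching Score
#'
#' Fraction of pairwise comparisons in a sample that agree with a rank
#' template — one minus the normalized Hamming distance. Always an exact
#' rational k/|pairs| in \[0, 1\].
#'
#' @param v A [pair_comparison_vector()] result (or bare 0/1 vector).
#' @param rt A [build_rank_template()] result.
#' @return Numeric scalar in \[0, 1\].
#' @export
rank_matching_score <- function(v, rt) {
  bits <- if (inherits(v, "pair_comparison")) {
    check_same_pairs(v$pairs, rt$pairs)
    v$bits
  } else {
    if (length(v) != length(rt$bits)) stop("bit-vector length mismatch", call. = FALSE)
    as.integer(v)
  }
  mean(bits == rt$bits)
}

#' Rank Difference Score
#'
#' RMS under one class's template minus RMS under another's; the per-set
#' feature consumed by the multi-network classifier. Antisymmetric in the
#' two templates and bounded in \[-1, 1\].
#'
#' @param v A [pair_comparison_vector()] result.
#' @param rt_a,rt_b Rank templates sharing the pair index of `v`.
#' @return Numeric scalar in \[-1, 1\].
#' @export
rank_difference_score <- function(v, rt_a, rt_b) {
  rank_matching_score(v, rt_a) - rank_matching_score(v, rt_b)
}

# fast path: RMS of every column of a bit matrix against template bits
rms_columns <- function(bits, rt) colMeans(bits == rt$bits)

#' Rank Matching Score profile
#'
#' RMS of every sample against every (gene set, class) template.
#'
#' @param m A [dirac_expr] or matrix.
#' @param templates A list of [rank_template][build_rank_template()] objects
#'   covering every (set, class) combination of interest.
#' @return A tibble with columns `sample_id`, `set_name`, `class_name`,
#'   `rms`, ordered by sorted set then class names.
#' @export
rms_profile <- function(m, templates) {
  v <- if (inherits(m, "dirac_expr")) m$values else m
  ord <- order(vapply(templates, `[[`, "", "set_name"),
               vapply(templates, `[[`, "", "class_name"))
  purrr::map_dfr(templates[ord], function(rt) {
    b <- pair_bits(v, rt$pairs)
    tibble::tibble(sample_id = colnames(v),
                   set_name = rt$set_name,
                   class_name = rt$class_name,
                   rms = unname(rms_columns(b, rt)))
  })
}

#' Build templates for every (set, class) combination
#'
#' @param m A [dirac_expr] with class labels (or supply `labels`).
#' @param gs A [geneset_collection], already coverage-filtered.
#' @param labels Optional named class labels overriding `m$labels`.
#' @return Named list of rank templates, names `"<set>|<class>"`.
#' @export
build_templates <- function(m, gs, labels = NULL) {
  m <- as_dirac_expr(m)
  lab <- require_labels(m, labels)
  classes <- sort(unique(lab))
  out <- list()
  for (s in sort(names(gs))) {
    for (cl in classes) {
      out[[paste0(s, "|", cl)]] <- build_rank_template(
        m, gs[[s]], sample_ids(m)[lab == cl], set_name = s, class_name = cl)
    }
  }
  out
}

#' Regulation contrast (tight vs loose)
#'
#' Quantifies how much more conserved a gene set's within-sample ordering is
#' inside a class than outside it: the mean RMS of in-class samples under the
#' in-class template minus the mean RMS of the remaining samples under the
#' same template. Positive values indicate tight regulation in the class,
#' negative values loose regulation.
#'
#' @param profile A tibble from [rms_profile()].
#' @param labels Named class labels covering the profile's samples.
#' @param class_name,set_name The (class, set) combination to contrast.
#' @return A one-row tibble: `set_name`, `class_name`, `delta`, `direction`
#'   (`"tight"`, `"loose"` or `"none"`).
#' @export
regulation_contrast <- function(profile, labels, class_name, set_name) {
  if (!class_name %in% labels) {
    stop("class '", class_name, "' absent from labels", call. = FALSE)
  }
  p <- profile[profile$set_name == set_name &
                 profile$class_name == class_name, , drop = FALSE]
  if (!nrow(p)) stop("profile lacks (set, class) = ('", set_name, "', '",
                     class_name, "')", call. = FALSE)
  lab <- labels[p$sample_id]
  in_cl <- lab == class_name
  if (all(in_cl)) stop("no out-of-class samples for contrast", call. = FALSE)
  delta <- mean(p$rms[in_cl]) - mean(p$rms[!in_cl])
  tibble::tibble(set_name = set_name, class_name = class_name, delta = delta,
                 direction = if (delta > 0) "tight" else
                   if (delta < 0) "loose" else "none")
}

#' Regulation contrasts for every (set, class) combination
#'
#' @inheritParams build_templates
#' @return A tibble of contrasts, one row per (set, class).
#' @export
regulation_contrasts <- function(m, gs, labels = NULL) {
  m <- as_dirac_expr(m)
  lab <- require_labels(m, labels)
  templates <- build_templates(m, gs, lab)
  prof <- rms_profile(m, templates)
  combos <- unique(prof[, c("set_name", "class_name")])
  purrr::pmap_dfr(combos, function(set_name, class_name) {
    regulation_contrast(prof, lab, class_name, set_name)
  })
}

#' Serialize / restore rank templates as JSON
#'
#' Versioned, portable representation (gene order, pair probabilities, bits)
#' so templates estimated on one cohort can score another.
#'
#' @param templates Named list of rank templates.
#' @param path Output / input path.
#' @return `write_templates` returns `path` invisibly; `read_templates` the
#'   template list.
#' @export
write_templates <- function(templates, path) {
  doc <- list(format = "diracnet-templates", version = 1L,
              templates = lapply(templates, function(rt) {
                list(set_name = rt$set_name, class_name = rt$class_name,
                     genes = rt$pairs$genes,
                     probabilities = unname(rt$probabilities),
                     bits = rt$bits)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(doc$format, "diracnet-templates")) {
    stop("not a diracnet template file: ", path, call. = FALSE)
  }
  out <- lapply(doc$templates, function(t) {
    pairs <- gene_pairs(t$genes)
    structure(list(set_name = t$set_name, class_name = t$class_name,
                   pairs = pairs,
                   probabilities = setNames(as.numeric(t$probabilities), pairs$labels),
                   bits = as.integer(t$bits)),
              class = "rank_template")
  })
  names(out) <- names(doc$templates)
  out
}
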