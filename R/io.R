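#' Read a delimited expression table
#'
#' Expects gene (or probe) identifiers in the first column and sample
#' identifiers in the header row, with a numeric body. Duplicate sample IDs
#' are rejected; non-numeric cells raise a parse error naming the offending
#' row and column.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter, `"\t"` by default.
#' @param labels_path,batches_path Optional paths to two-column files
#'   (sample_id, value) read with [read_sample_annotation()].
#' @return A [dirac_expr] object.
#' @export
read_expression_table <- function(path, delimiter = "\t",
                                  labels_path = NULL, batches_path = NULL) {
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           row.names = NULL, comment.char = "", quote = "\"")
  if (ncol(raw) < 2) stop("expression table needs an ID column and at least one sample", call. = FALSE)
  ids <- as.character(raw[[1]])
  samp <- colnames(raw)[-1]
  if (anyDuplicated(samp)) {
    stop("duplicate sample IDs in header: ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene/probe IDs in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  body <- raw[-1]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop(sprintf("non-numeric value %s at row '%s', column '%s'",
                     dQuote(col[bad[1]]), ids[bad[1]], samp[j]), call. = FALSE)
      }
      body[[j]] <- num
    }
  }
  values <- as.matrix(body)
  dimnames(values) <- list(ids, samp)
  labels  <- if (!is.null(labels_path))  read_sample_annotation(labels_path)
  batches <- if (!is.null(batches_path)) read_sample_annotation(batches_path)
  dirac_expr(values, labels = labels, batches = batches)
}

#' Write an expression table
#'
#' @param m A [dirac_expr] or genes x samples matrix.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, delimiter = "\t") {
  v <- if (inherits(m, "dirac_expr")) m$values else m
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample annotation file
#'
#' @param path Path to a headerless or headered two-column TSV
#'   (sample_id, value). A header line is detected and skipped when the
#'   first field equals `"sample_id"`.
#' @param delimiter Field delimiter.
#' @return Named character vector (names = sample IDs).
#' @export
read_sample_annotation <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, sep = delimiter, header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2) stop("annotation file must have two columns", call. = FALSE)
  if (identical(tolower(df[1, 1]), "sample_id")) df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df[[1]])) {
    stop("duplicate sample IDs in annotation file", call. = FALSE)
  }
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write a two-column sample annotation file
#'
#' @param ann Named character vector (names = sample IDs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(ann, path) {
  utils::write.table(data.frame(names(ann), unname(ann)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene level
#'
#' Replaces probe rows by per-gene arithmetic means across the probes that
#' interrogate each gene. Probes absent from the map are dropped with a
#' message (annotation gaps are common); output genes are ordered
#' lexicographically so downstream pair indexing is reproducible.
#'
#' @param m A [dirac_expr] with probe IDs as rownames.
#' @param probe_to_gene Named character vector mapping probe ID -> gene ID.
#' @return A [dirac_expr] with one row per distinct gene.
#' @export
collapse_probes <- function(m, probe_to_gene) {
  m <- as_dirac_expr(m)
  if (length(probe_to_gene) == 0) stop("empty probe-to-gene mapping", call. = FALSE)
  probes <- gene_ids(m)
  mapped <- probes[probes %in% names(probe_to_gene)]
  dropped <- setdiff(probes, mapped)
  if (length(dropped)) {
    message(length(dropped), " unmapped probe(s) dropped")
  }
  if (!length(mapped)) stop("all probes unmapped; check the mapping", call. = FALSE)
  gene <- probe_to_gene[mapped]
  v <- rowsum(m$values[mapped, , drop = FALSE], group = gene, reorder = TRUE)
  v <- v / as.vector(table(gene)[rownames(v)])
  dirac_expr(v, labels = m$labels, batches = m$batches)
}

#' Gene set collections
#'
#' A named list of character vectors (gene IDs), with set names unique and
#' genes unique within each set.
#'
#' @param sets Named list of character vectors.
#' @param provenance Free-text provenance string.
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, provenance = "") {
  if (length(sets) && (is.null(names(sets)) || anyDuplicated(names(sets)))) {
    stop("gene set names must be present and unique", call. = FALSE)
  }
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    if (anyDuplicated(g)) stop("duplicate genes within a set", call. = FALSE)
    g
  })
  structure(sets, class = "geneset_collection", provenance = provenance)
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("<geneset_collection> ", length(x), " sets, ",
      length(unique(unlist(x))), " unique genes\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line,
#' `set_name TAB description TAB gene1 TAB gene2 ...`. Duplicate genes within
#' a line are deduplicated with a warning; the description fields are kept as
#' provenance.
#'
#' @param path Path to a GMT file.
#' @return A [geneset_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(geneset_collection(setNames(list(), character()),
                              provenance = paste0("GMT: ", path)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  names_ <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names_)) stop("duplicate set names in GMT", call. = FALSE)
  desc <- vapply(fields, `[[`, "", 2)
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warning("duplicate genes within set '", f[[1]], "' deduplicated")
      g <- unique(g)
    }
    g
  })
  names(sets) <- names_
  geneset_collection(sets, provenance = paste0("GMT: ", path, "; ",
                                               paste(desc, collapse = " | ")))
}

#' Write a GMT gene-set file
#'
#' @param gs A [geneset_collection].
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gs, path, description = "na") {
  lines <- vapply(names(gs), function(nm) {
    paste(c(nm, description, gs[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by data coverage
#'
#' Retains a set when at least `min_fraction` of its genes and at least
#' `min_present` genes are measured in the data, and replaces the set by its
#' intersection with the measured genes in lexicographic order (the canonical
#' order used for pair indexing). Per-set coverage fractions are attached as
#' attribute `"coverage"`.
#'
#' @param gs A [geneset_collection].
#' @param m A [dirac_expr] (or matrix) defining the measured gene universe.
#' @param min_fraction Minimum fraction of set genes present, default 0.30.
#' @param min_present Minimum absolute number of present genes, default 5
#'   (pairwise templates on fewer genes are degenerate).
#' @return A filtered [geneset_collection].
#' @export
filter_genesets <- function(gs, m, min_fraction = 0.30, min_present = 5) {
  stopifnot(inherits(gs, "geneset_collection"),
            min_fraction > 0, min_fraction <= 1)
  universe <- if (inherits(m, "dirac_expr")) gene_ids(m) else
    if (is.matrix(m)) rownames(m) else as.character(m)
  inter <- lapply(gs, function(g) sort(intersect(g, universe)))
  frac <- vapply(seq_along(gs), function(i) {
    length(inter[[i]]) / length(gs[[i]])
  }, 0)
  names(frac) <- names(gs)
  keep <- frac >= min_fraction & lengths(inter) >= min_present
  if (!any(keep)) {
    stop("no gene set passes coverage filtering; relax `min_fraction`/`min_present`",
         call. = FALSE)
  }
  out <- geneset_collection(inter[keep], provenance = attr(gs, "provenance"))
  attr(out, "coverage") <- frac
  out
}
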