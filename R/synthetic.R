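#' Simulation configuration for subtype-structured expression data
#'
#' Describes a synthetic multi-subtype cohort on the log2 scale (emitted on
#' the raw intensity scale, `2^latent`): background genes with i.i.d. noise
#' around gene-specific baselines, optional planted differentially expressed
#' genes, and gene sets whose within-sample rank ordering is either *tight*
#' in a class (a fixed latent ordering with adjacent-rank spacing `delta`
#' and per-sample gaussian noise `sigma`) or *loose* (the ordering is
#' redrawn for every sample). Regulation strength is parameterized by
#' `delta/sigma` rather than by a target matching score, which is an
#' emergent statistic ([conservation_index()] reports what was achieved).
#'
#' @param classes Class names.
#' @param n_per_class Samples per class (recycled).
#' @param n_background Number of background genes.
#' @param sets List of set specs: each a list with `name`, `size`,
#'   `regulation` (named character, per class `"tight"`/`"loose"`), `delta`,
#'   `sigma`.
#' @param n_planted Number of planted discriminative genes (0 disables).
#' @param planted_effect Mean shift of a planted gene in its assigned class,
#'   in units of the unit background noise SD.
#' @param test_fraction Fraction of each class assigned to batch `"b2"`
#'   (the held-out cohort); the remainder is batch `"b1"`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(classes = c("A", "B"),
                       n_per_class = 60,
                       n_background = 500,
                       sets = default_sets(classes),
                       n_planted = 0,
                       planted_effect = 1.5,
                       test_fraction = 1/3) {
  n_per_class <- rep_len(n_per_class, length(classes))
  if (any(n_per_class < 3)) stop("each class needs at least 3 samples", call. = FALSE)
  for (s in sets) {
    stopifnot(!is.null(s$name), s$size >= 2, s$sigma >= 0, s$delta > 0)
    if (!all(classes %in% names(s$regulation))) {
      stop("set '", s$name, "': regulation must name every class", call. = FALSE)
    }
  }
  structure(list(classes = classes, n_per_class = n_per_class,
                 n_background = n_background, sets = sets,
                 n_planted = n_planted, planted_effect = planted_effect,
                 test_fraction = test_fraction),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_sets <- function(classes = c("A", "B")) {
  tight <- setNames(rep("loose", length(classes)), classes)
  tight[classes[1]] <- "tight"
  loose <- setNames(rep("loose", length(classes)), classes)
  list(list(name = "TIGHT_A", size = 20, regulation = tight,
            delta = 1.5, sigma = 0.5),
       list(name = "LOOSE", size = 20, regulation = loose,
            delta = 1.5, sigma = 0.5))
}

set_offsets <- function(perm, delta) (order(perm) - (length(perm) + 1) / 2) * delta

#' Generate a synthetic expression dataset with known regulation structure
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the output is byte-reproducible given
#'   (config, seed).
#' @return List with `expr` (a [dirac_expr] on the raw positive scale, with
#'   class labels and batches) and `truth` (gene sets, latent orderings,
#'   regulation modes, planted genes, discriminative genes, batch labels).
#' @export
generate_dataset <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  classes <- cfg$classes
  labels <- rep(classes, cfg$n_per_class)
  samples <- unlist(lapply(seq_along(classes), function(k) {
    sprintf("%s_s%03d", classes[k], seq_len(cfg$n_per_class[k]))
  }))
  names(labels) <- samples
  n <- length(samples)

  # batch assignment, stratified per class
  batches <- setNames(rep("b1", n), samples)
  if (cfg$test_fraction > 0) {
    for (cl in classes) {
      ids <- samples[labels == cl]
      n2 <- round(length(ids) * cfg$test_fraction)
      if (n2 > 0) batches[sample(ids, n2)] <- "b2"
    }
  }

  blocks <- list()
  # background genes: gene-specific baseline, unit noise
  if (cfg$n_background > 0) {
    base <- runif(cfg$n_background, 6, 10)
    bg <- matrix(rnorm(cfg$n_background * n, mean = base, sd = 1),
                 nrow = cfg$n_background,
                 dimnames = list(sprintf("BG%04d", seq_len(cfg$n_background)),
                                 samples))
    blocks$bg <- bg
  }

  # planted discriminative genes, assigned round-robin across classes
  planted_genes <- character()
  planted_class <- character()
  if (cfg$n_planted > 0) {
    planted_genes <- sprintf("DE%03d", seq_len(cfg$n_planted))
    planted_class <- classes[((seq_len(cfg$n_planted) - 1) %% length(classes)) + 1]
    names(planted_class) <- planted_genes
    de <- matrix(rnorm(cfg$n_planted * n, mean = 8, sd = 1),
                 nrow = cfg$n_planted,
                 dimnames = list(planted_genes, samples))
    for (i in seq_len(cfg$n_planted)) {
      hit <- labels == planted_class[i]
      de[i, hit] <- de[i, hit] + cfg$planted_effect
    }
    blocks$de <- de
  }

  # regulated gene sets
  orderings <- list()
  modes <- list()
  set_list <- list()
  for (s in cfg$sets) {
    genes <- sprintf("%s_G%02d", s$name, seq_len(s$size))
    set_list[[s$name]] <- genes
    x <- matrix(0, s$size, n, dimnames = list(genes, samples))
    for (cl in classes) {
      idx <- which(labels == cl)
      mode <- s$regulation[[cl]]
      modes[[paste0(s$name, "|", cl)]] <- mode
      if (mode == "tight") {
        perm <- sample(s$size)            # perm[r] = gene index at rank r
        orderings[[paste0(s$name, "|", cl)]] <- genes[perm]
        off <- set_offsets(perm, s$delta)
        x[, idx] <- 8 + off +
          matrix(rnorm(s$size * length(idx), 0, s$sigma), s$size)
      } else {
        for (j in idx) {
          perm <- sample(s$size)
          x[, j] <- 8 + set_offsets(perm, s$delta) + rnorm(s$size, 0, s$sigma)
        }
      }
    }
    blocks[[s$name]] <- x
  }

  latent <- do.call(rbind, blocks)
  expr <- dirac_expr(2^latent, labels = labels, batches = batches)
  tight_sets <- unique(vapply(cfg$sets, function(s)
    if (any(s$regulation == "tight")) s$name else NA_character_, ""))
  tight_sets <- tight_sets[!is.na(tight_sets)]
  disc <- c(planted_genes, unlist(set_list[tight_sets], use.names = FALSE))
  truth <- list(gene_sets = geneset_collection(set_list,
                                               provenance = "synthetic regulated sets"),
                orderings = orderings, modes = modes,
                planted_genes = planted_genes,
                planted_class = planted_class,
                discriminative_genes = disc,
                batches = batches, config = cfg, seed = seed)
  list(expr = expr, truth = truth)
}

#' Achieved rank conservation per (set, class)
#'
#' Mean in-class RMS under the in-class template — the calibration readout
#' for [sim_config()] parameters.
#'
#' @param m A [dirac_expr] with labels (or supply `labels`).
#' @param gs A [geneset_collection].
#' @param labels Optional named class labels.
#' @return Tibble with `set_name`, `class_name`, `conservation` in \[0, 1\].
#' @export
conservation_index <- function(m, gs, labels = NULL) {
  m <- as_dirac_expr(m)
  lab <- require_labels(m, labels)
  prof <- rms_profile(m, build_templates(m, gs, lab))
  prof |>
    dplyr::filter(lab[.data$sample_id] == .data$class_name) |>
    dplyr::group_by(.data$set_name, .data$class_name) |>
    dplyr::summarise(conservation = mean(.data$rms), .groups = "drop")
}

#' Preprocessing-variant emulators
#'
#' Six transform families emulating the downstream effect of common
#' microarray preprocessing pipelines on a raw positive-scale matrix:
#' \describe{
#'   \item{V1}{log2 transform.}
#'   \item{V2}{log2 then quantile normalization to the pooled reference
#'     distribution.}
#'   \item{V3}{per-sample affine rescaling (`scale * x + offset`).}
#'   \item{V4}{per-sample multiplicative scaling to a common median.}
#'   \item{V5}{background subtraction with flooring at a threshold —
#'     tie-inducing, hence *not* rank-preserving.}
#'   \item{V6}{V5 followed by quantile normalization.}
#' }
#' V1-V4 are strictly increasing within each sample, so all pairwise
#' comparison bits are unchanged on tie-free data; V5/V6 floor the lower
#' tail and perturb rank-based features.
#'
#' @param m A [dirac_expr] or matrix, positive-valued for the log variants.
#' @param variant One of `"V1"`..`"V6"`.
#' @param seed Seed for V3's random per-sample coefficients (when `scale` /
#'   `offset` are not given).
#' @param scale,offset V3 coefficients, scalar or per-sample vectors;
#'   `NULL` draws them per sample (`scale` uniform on \[0.7, 1.4\], `offset`
#'   uniform on \[0, median(sample)/2\], an additive background comparable
#'   to the lower signal range).
#' @param floor_quantile,floor_value V5/V6 background quantile (per sample)
#'   and floor.
#' @return A [dirac_expr] with attributes `"variant"` and
#'   `"rank_preserving"`.
#' @export
apply_preprocessing_variant <- function(m, variant, seed = 1,
                                        scale = NULL, offset = NULL,
                                        floor_quantile = 0.2, floor_value = 1) {
  m <- as_dirac_expr(m)
  variant <- match.arg(variant, paste0("V", 1:6))
  x <- m$values
  if (variant %in% c("V1", "V2") && any(x <= 0)) {
    stop("log variant ", variant, " requires strictly positive values",
         call. = FALSE)
  }
  y <- switch(variant,
    V1 = log2(x),
    V2 = {
      q <- limma::normalizeQuantiles(log2(x))
      dimnames(q) <- dimnames(x)
      q
    },
    V3 = {
      if (is.null(scale)) {
        set.seed(seed)
        scale <- runif(ncol(x), 0.7, 1.4)
        # additive background comparable to the lower signal range
        offset <- runif(ncol(x), 0, 0.5 * apply(x, 2, median))
      }
      if (is.null(offset)) offset <- 0
      scale <- rep_len(scale, ncol(x)); offset <- rep_len(offset, ncol(x))
      if (any(scale <= 0)) stop("V3 scale must be positive", call. = FALSE)
      sweep(sweep(x, 2, scale, "*"), 2, offset, "+")
    },
    V4 = {
      med <- apply(x, 2, median)
      sweep(x, 2, median(med) / med, "*")
    },
    V5 = floor_variant(x, floor_quantile, floor_value),
    V6 = {
      q <- limma::normalizeQuantiles(floor_variant(x, floor_quantile, floor_value))
      dimnames(q) <- dimnames(x)
      q
    })
  out <- dirac_expr(y, labels = m$labels, batches = m$batches)
  attr(out, "variant") <- variant
  attr(out, "rank_preserving") <- variant %in% c("V1", "V2", "V3", "V4")
  out
}

floor_variant <- function(x, floor_quantile, floor_value) {
  bg <- apply(x, 2, quantile, probs = floor_quantile, names = FALSE)
  pmax(sweep(x, 2, bg), floor_value)
}

#' Inject a synthetic batch effect
#'
#' Two mechanisms with opposite relationships to rank-based features:
#' `"gene_shift"` adds a per-(batch, gene) offset drawn from
#' `N(0, magnitude^2)` — this reorders genes within samples and perturbs
#' both value- and rank-based classifiers; `"sample_monotone"` applies a
#' per-sample strictly increasing distortion
#' (`a * x^g`, positive data) — this leaves every pairwise comparison, and
#' hence all rank-conservation features, exactly unchanged.
#'
#' @param m A [dirac_expr] (batches taken from it unless `batch_map` given).
#' @param mode `"gene_shift"` or `"sample_monotone"`.
#' @param magnitude Effect size: offset SD for `gene_shift`; distortion
#'   range for `sample_monotone` (0 = identity).
#' @param seed Integer seed.
#' @param batch_map Optional named batch labels covering all samples.
#' @param reference Optional batch left unshifted under `gene_shift`
#'   (offsets are relative to it).
#' @return A perturbed [dirac_expr].
#' @export
inject_batch_effect <- function(m, mode = c("gene_shift", "sample_monotone"),
                                magnitude = 1, seed = 1, batch_map = NULL,
                                reference = NULL) {
  m <- as_dirac_expr(m)
  mode <- match.arg(mode)
  bm <- if (is.null(batch_map)) m$batches else
    check_sample_annotation(batch_map, sample_ids(m), "batch_map")
  if (mode == "gene_shift" && is.null(bm)) {
    stop("gene_shift requires batch labels covering all samples", call. = FALSE)
  }
  set.seed(seed)
  x <- m$values
  if (mode == "gene_shift") {
    for (b in sort(unique(bm))) {
      delta <- rnorm(nrow(x), 0, magnitude)
      if (!is.null(reference) && b == reference) next
      x[, bm == b] <- x[, bm == b] + delta
    }
  } else {
    if (magnitude > 0 && any(x <= 0)) {
      stop("sample_monotone requires positive values", call. = FALSE)
    }
    a <- exp(runif(ncol(x), -magnitude, magnitude))
    g <- exp(runif(ncol(x), -magnitude / 4, magnitude / 4))
    for (j in seq_len(ncol(x))) x[, j] <- a[j] * x[, j]^g[j]
  }
  dirac_expr(x, labels = m$labels, batches = m$batches)
}

#' Location-scale batch correction
#'
#' Per batch and gene, centers and scales to the batch moments, then
#' restores the pooled per-gene mean and standard deviation (population
#' moments, which makes the operation an exact fixed point). This is a
#' deliberately simple location-scale adjustment capturing what the
#' robustness experiments need; it is not an empirical-Bayes method.
#'
#' @param m A [dirac_expr] with batch labels (or supply `batch_map`).
#' @param batch_map Optional named batch labels.
#' @return A corrected [dirac_expr].
#' @export
simple_batch_correct <- function(m, batch_map = NULL) {
  m <- as_dirac_expr(m)
  bm <- if (is.null(batch_map)) m$batches else
    check_sample_annotation(batch_map, sample_ids(m), "batch_map")
  if (is.null(bm)) stop("batch labels required", call. = FALSE)
  x <- m$values
  sizes <- table(bm)
  if (any(sizes < 2)) {
    stop("batch(es) with a single sample cannot be corrected: ",
         paste(names(which(sizes < 2)), collapse = ", "), call. = FALSE)
  }
  mp <- rowMeans(x)
  sp <- sqrt(rowMeans((x - mp)^2))
  y <- x
  for (b in unique(bm)) {
    idx <- bm == b
    mb <- rowMeans(x[, idx, drop = FALSE])
    sb <- sqrt(rowMeans((x[, idx, drop = FALSE] - mb)^2))
    sb_safe <- ifelse(sb > 0, sb, 1)
    z <- (x[, idx, drop = FALSE] - mb) / sb_safe
    y[, idx] <- z * sp + mp
  }
  dirac_expr(y, labels = m$labels, batches = m$batches)
}
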