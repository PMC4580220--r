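test_that("generation is byte-reproducible from (config, seed)", {
  cfg <- sim_config(n_per_class = 8, n_background = 40)
  a <- generate_dataset(cfg, seed = 42)
  b <- generate_dataset(cfg, seed = 42)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth$orderings, b$truth$orderings)
  c_ <- generate_dataset(cfg, seed = 43)
  expect_false(identical(a$expr$values, c_$expr$values))
})

test_that("a noiseless tight set reproduces its latent ordering exactly", {
  cfg <- sim_config(n_per_class = 6, n_background = 10,
                    sets = list(list(name = "S", size = 6,
                                     regulation = c(A = "tight", B = "loose"),
                                     delta = 1, sigma = 0)),
                    test_fraction = 0)
  ds <- generate_dataset(cfg, seed = 2)
  ord <- ds$truth$orderings[["S|A"]]          # genes in ascending order
  p <- gene_pairs(ds$truth$gene_sets$S)
  latent_bits <- pair_comparison_vector(
    setNames(seq_along(ord), ord)[p$genes], p)$bits
  a_ids <- sample_ids(ds$expr)[ds$expr$labels == "A"]
  for (s in a_ids) {
    v <- pair_comparison_vector(ds$expr$values[p$genes, s], p)
    expect_bits_equal(v$bits, latent_bits)
  }
  ci <- conservation_index(ds$expr, ds$truth$gene_sets)
  expect_equal(ci$conservation[ci$class_name == "A"], 1)
})

test_that("loose sets show near-zero contrast and tight margins grow as noise shrinks", {
  deltas <- sapply(c(0.25, 2), function(sg) {
    mean(sapply(1:3, function(s) {
      cfg <- sim_config(n_per_class = 40, n_background = 10,
                        sets = list(list(name = "S", size = 10,
                                         regulation = c(A = "tight", B = "loose"),
                                         delta = 1, sigma = sg)),
                        test_fraction = 0)
      ds <- generate_dataset(cfg, seed = s)
      co <- regulation_contrasts(ds$expr, ds$truth$gene_sets)
      co$delta[co$class_name == "A"]
    }))
  })
  expect_gt(deltas[1], deltas[2])   # tighter regulation, larger margin
  expect_gt(deltas[1], 0.3)

  # fully loose set: contrast close to zero for both classes
  cfg <- sim_config(n_per_class = 60, n_background = 10,
                    sets = list(list(name = "L", size = 10,
                                     regulation = c(A = "loose", B = "loose"),
                                     delta = 1, sigma = 0.5)),
                    test_fraction = 0)
  d <- sapply(1:3, function(s) {
    ds <- generate_dataset(cfg, seed = 10 + s)
    co <- regulation_contrasts(ds$expr, ds$truth$gene_sets)
    max(abs(co$delta))
  })
  expect_lt(mean(d), 0.12)
})

test_that("rank-preserving variants leave comparison bits untouched", {
  ds <- small_regulated_expr(seed = 13, n_per_class = 6)
  p <- gene_pairs(ds$truth$gene_sets$S1)
  bits0 <- pair_bits_of(ds$expr$values, p)
  for (vr in c("V1", "V2", "V3", "V4")) {
    out <- apply_preprocessing_variant(ds$expr, vr, seed = 99)
    expect_true(attr(out, "rank_preserving"))
    expect_identical(pair_bits_of(out$values, p), bits0)
  }
  # V3 with unit scale and zero offset is the identity
  ident <- apply_preprocessing_variant(ds$expr, "V3", scale = 1, offset = 0)
  expect_equal(ident$values, ds$expr$values)
  # log variants refuse non-positive input
  neg <- ds$expr$values; neg[1, 1] <- -1
  expect_error(apply_preprocessing_variant(dirac_expr(neg, ds$expr$labels), "V1"),
               "positive")
})

test_that("the flooring variant perturbs only pairs involving floored genes", {
  ds <- small_regulated_expr(seed = 14, n_per_class = 6)
  out <- apply_preprocessing_variant(ds$expr, "V5", floor_quantile = 0.25)
  expect_false(attr(out, "rank_preserving"))
  genes <- sort(gene_ids(ds$expr))
  p <- gene_pairs(genes)
  b0 <- pair_bits_of(ds$expr$values, p)
  b1 <- pair_bits_of(out$values, p)
  expect_gt(sum(b0 != b1), 0)                  # some bits must change
  # locality: a changed bit involves at least one floored gene in that sample
  floored <- out$values == min(out$values)
  changed <- which(b0 != b1, arr.ind = TRUE)
  for (r in seq_len(min(nrow(changed), 50))) {
    pr <- changed[r, 1]; sm <- changed[r, 2]
    gi <- p$genes[p$i[pr]]; gj <- p$genes[p$j[pr]]
    expect_true(floored[gi, sm] || floored[gj, sm])
  }
})

test_that("batch-effect injection behaves per mode", {
  ds <- small_regulated_expr(seed = 15, n_per_class = 8)
  m <- apply_preprocessing_variant(ds$expr, "V1")
  bm <- setNames(rep(c("b1", "b2"), length.out = ncol(m$values)), sample_ids(m))

  # zero magnitude is the identity in both modes
  for (mode in c("gene_shift", "sample_monotone")) {
    out <- inject_batch_effect(m, mode = mode, magnitude = 0, batch_map = bm)
    expect_equal(out$values, m$values)
  }
  expect_error(inject_batch_effect(m, mode = "nope", batch_map = bm))

  # per-sample monotone distortion preserves RMS features exactly
  tpl <- build_templates(m, ds$truth$gene_sets)
  prof0 <- rms_profile(m, tpl)
  mono <- inject_batch_effect(m, mode = "sample_monotone", magnitude = 1,
                              seed = 5, batch_map = bm)
  expect_equal(rms_profile(mono, tpl)$rms, prof0$rms)

  # gene shifts separate batch means increasingly with magnitude
  tstats <- sapply(c(0.5, 2, 6), function(mag) {
    out <- inject_batch_effect(m, mode = "gene_shift", magnitude = mag,
                               seed = 6, batch_map = bm)
    mean(abs(apply(out$values, 1, function(v)
      t.test(v[bm == "b1"], v[bm == "b2"])$statistic)))
  })
  expect_true(all(diff(tstats) > 0))
})

test_that("location-scale correction removes gene shifts and is a fixed point", {
  ds <- small_regulated_expr(seed = 16, n_per_class = 10)
  m <- ds$expr
  bm <- setNames(rep(c("b1", "b2"), each = ncol(m$values) / 2), sample_ids(m))

  shifted <- inject_batch_effect(m, mode = "gene_shift", magnitude = 3,
                                 seed = 7, batch_map = bm)
  corr <- simple_batch_correct(shifted, batch_map = bm)
  gap <- rowMeans(corr$values[, bm == "b1"]) - rowMeans(corr$values[, bm == "b2"])
  expect_lt(max(abs(gap)), 1e-8)

  twice <- simple_batch_correct(corr, batch_map = bm)
  expect_equal(twice$values, corr$values, tolerance = 1e-10)

  # single batch: correction is the identity
  single <- simple_batch_correct(m, batch_map = setNames(rep("b1", ncol(m$values)),
                                                         sample_ids(m)))
  expect_equal(single$values, m$values, tolerance = 1e-10)

  bm_bad <- bm; bm_bad[1] <- "solo"
  expect_error(simple_batch_correct(m, batch_map = bm_bad), "single sample")
})
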