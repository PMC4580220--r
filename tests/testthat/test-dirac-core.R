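test_that("pairwise comparison bits follow the strict-inequality rule", {
  p <- gene_pairs(c("g1", "g2", "g3"))
  expect_bits_equal(pair_comparison_vector(c(g1 = 1, g2 = 2, g3 = 3), p)$bits,
                    c(1, 1, 1))
  expect_bits_equal(pair_comparison_vector(c(g1 = 3, g2 = 2, g3 = 1), p)$bits,
                    c(0, 0, 0))
  # ties are 0: g1 < g2 is false at (2, 2)
  expect_bits_equal(pair_comparison_vector(c(g1 = 2, g2 = 2, g3 = 5), p)$bits,
                    c(0, 1, 1))
  expect_error(pair_comparison_vector(c(g1 = NaN, g2 = 1, g3 = 2), p),
               "non-finite")
})

test_that("rank templates reproduce the hand-counted example", {
  m <- toy_matrix()
  rt <- build_rank_template(m, rownames(m), colnames(m))
  expect_equal(unname(rt$probabilities), c(2/3, 1, 2/3))
  expect_bits_equal(rt$bits, c(1, 1, 1))

  # single sample: template equals that sample's comparison vector
  rt1 <- build_rank_template(m, rownames(m), "s2")
  v2 <- pair_comparison_vector(m[, "s2"], rt1$pairs)
  expect_bits_equal(rt1$bits, v2$bits)

  # two opposite orderings: probabilities 0.5, strict rule gives all zeros
  opp <- matrix(c(1, 2, 3, 3, 2, 1), 3,
                dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  rt0 <- build_rank_template(opp, rownames(opp), colnames(opp))
  expect_true(all(rt0$probabilities == 0.5))
  expect_bits_equal(rt0$bits, c(0, 0, 0))

  expect_error(build_rank_template(m, rownames(m), character()), "empty class")
})

test_that("rank matching and difference scores match direct bit counting", {
  m <- toy_matrix()
  rt <- build_rank_template(m, rownames(m), colnames(m))
  p <- rt$pairs
  rms <- vapply(colnames(m), function(s)
    rank_matching_score(pair_comparison_vector(m[, s], p), rt), 0)
  expect_equal(unname(rms), c(1, 2/3, 2/3))
  expect_equal(mean(rms), 7/9)

  # extremes
  v <- pair_comparison_vector(m[, "s1"], p)
  expect_equal(rank_matching_score(v$bits, rt), 1)
  expect_equal(rank_matching_score(1 - rt$bits, rt), 0)

  # mismatched pair index is an error
  p2 <- gene_pairs(c("h1", "h2", "h3"))
  v2 <- pair_comparison_vector(c(h1 = 1, h2 = 2, h3 = 3), p2)
  expect_error(rank_matching_score(v2, rt), "pair indices differ")

  # RDS: identical templates give 0, extremes give +1, antisymmetry holds
  expect_equal(rank_difference_score(v, rt, rt), 0)
  rt_c <- rt; rt_c$bits <- 1L - rt$bits
  expect_equal(rank_difference_score(v, rt, rt_c), 1)
  expect_equal(rank_difference_score(v, rt_c, rt), -1)
})

test_that("random RDS values equal the brute-force difference of bit counts", {
  set.seed(11)
  p <- gene_pairs(sprintf("g%d", 1:4))       # 6 pairs
  for (i in 1:25) {
    x <- setNames(runif(4), p$genes)
    ta <- tb <- build_rank_template(matrix(runif(8), 4, dimnames = list(p$genes, c("a", "b"))),
                                    p$genes, c("a", "b"))
    ta$bits <- as.integer(runif(6) > 0.5)
    tb$bits <- as.integer(runif(6) > 0.5)
    v <- pair_comparison_vector(x, p)
    expect_equal(rank_difference_score(v, ta, tb),
                 oracle_rms(v$bits, ta$bits) - oracle_rms(v$bits, tb$bits))
  }
})

test_that("rms_profile composes per-sample scores over sets and classes", {
  x <- random_expr(8, 10, seed = 4)
  lab <- setNames(rep(c("A", "B"), 5), colnames(x))
  gs <- geneset_collection(list(P1 = rownames(x)[1:5], P2 = rownames(x)[4:8]))
  tpl <- build_templates(dirac_expr(x, lab), gs)
  prof <- rms_profile(x, tpl)
  expect_equal(nrow(prof), 10 * 2 * 2)
  for (r in sample(nrow(prof), 12)) {
    row <- prof[r, ]
    rt <- tpl[[paste0(row$set_name, "|", row$class_name)]]
    v <- pair_comparison_vector(x[rt$pairs$genes, row$sample_id], rt$pairs)
    expect_equal(row$rms, oracle_rms(v$bits, rt$bits))
  }

  # identical samples give constant columns
  xx <- matrix(rep(x[, 1], 4), ncol = 4,
               dimnames = list(rownames(x), paste0("t", 1:4)))
  prof2 <- rms_profile(xx, tpl)
  for (g in split(prof2$rms, paste(prof2$set_name, prof2$class_name))) {
    expect_equal(length(unique(g)), 1L)
  }
})

test_that("regulation contrasts separate tight from loose regulation", {
  # extreme case: in-class samples match the template, out-class complement
  x <- matrix(c(1, 2, 3, 1, 2, 3, 3, 2, 1, 3, 2, 1), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("a1", "a2", "b1", "b2")))
  lab <- setNames(c("A", "A", "B", "B"), colnames(x))
  gs <- geneset_collection(list(P = c("g1", "g2", "g3")))
  prof <- rms_profile(x, build_templates(dirac_expr(x, lab), gs))
  cc <- regulation_contrast(prof, lab, "A", "P")
  expect_equal(cc$delta, 1)
  expect_identical(cc$direction, "tight")

  expect_error(regulation_contrast(prof, lab, "Z", "P"), "absent")

  # permuted labels: contrast concentrates near zero
  y <- random_expr(6, 200, seed = 9)
  gs2 <- geneset_collection(list(Q = rownames(y)))
  for (s in 1:3) {
    set.seed(s)
    lab2 <- setNames(sample(rep(c("A", "B"), 100)), colnames(y))
    prof2 <- rms_profile(y, build_templates(dirac_expr(y, lab2), gs2))
    d <- regulation_contrast(prof2, lab2, "A", "Q")$delta
    expect_lt(abs(d), 0.1)
  }
})

test_that("templates maximize summed training RMS (small enumeration)", {
  for (s in 1:20) {
    k <- sample(3:5, 1); n <- sample(3:7, 1)
    x <- random_expr(k, n, seed = 100 + s)
    rt <- build_rank_template(x, rownames(x), colnames(x))
    if (any(rt$probabilities == 0.5)) next
    bits <- pair_bits_of(x, rt$pairs)
    np <- length(rt$bits)
    cand <- as.matrix(expand.grid(rep(list(0:1), np)))
    scores <- apply(cand, 1, function(tb) sum(colSums(bits == tb) / np))
    expect_equal(sum(colSums(bits == rt$bits) / np), max(scores))
  }
})

test_that("template serialization round-trips", {
  m <- small_regulated_expr(seed = 3)
  tpl <- build_templates(apply_preprocessing_variant(m$expr, "V1"),
                         m$truth$gene_sets)
  path <- withr::local_tempfile(fileext = ".json")
  write_templates(tpl, path)
  back <- read_templates(path)
  expect_identical(names(back), names(tpl))
  for (nm in names(tpl)) {
    expect_identical(back[[nm]]$bits, tpl[[nm]]$bits)
    expect_equal(back[[nm]]$probabilities, tpl[[nm]]$probabilities)
    expect_identical(back[[nm]]$pairs$genes, tpl[[nm]]$pairs$genes)
  }
})
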