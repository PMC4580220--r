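test_that("stratified splits preserve class proportions", {
  ids9 <- sprintf("s%02d", 1:9)
  lab9 <- setNames(rep("A", 9), ids9)
  sp <- stratified_split(ids9, lab9, 2/3, seed = 1)
  expect_length(sp$part_a, 6); expect_length(sp$part_b, 3)

  ids10 <- sprintf("s%02d", 1:10)
  lab10 <- setNames(rep("A", 10), ids10)
  sp <- stratified_split(ids10, lab10, 2/3, seed = 1)
  expect_length(sp$part_a, 7); expect_length(sp$part_b, 3)  # ceil to part A

  ids45 <- sprintf("s%02d", 1:45)
  lab45 <- setNames(rep(c("A", "B"), c(30, 15)), ids45)
  sp <- stratified_split(ids45, lab45, 2/3, seed = 3)
  expect_equal(as.integer(table(lab45[sp$part_a])), c(20L, 10L))
  expect_setequal(c(sp$part_a, sp$part_b), ids45)

  expect_identical(stratified_split(ids45, lab45, 2/3, seed = 5),
                   stratified_split(ids45, lab45, 2/3, seed = 5))
  lab_bad <- setNames(rep(c("A", "B"), c(43, 2)), ids45)
  expect_error(stratified_split(ids45, lab_bad, 2/3, seed = 1), "fewer than 3")
})

test_that("moderated t reduces to the ordinary pooled t without shrinkage", {
  x <- random_expr(40, 20, seed = 21)
  lab <- setNames(rep(c("A", "B"), 10), colnames(x))
  res <- suppressWarnings(moderated_t_screen(x, lab, top_k = 40, prior_df = 0))
  # oracle: plain two-sample pooled-variance t per feature
  tt <- apply(x, 1, function(v) {
    a <- v[lab == "A"]; b <- v[lab == "B"]
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  })
  expect_equal(res$statistic, unname(tt[res$feature]))
  expect_identical(res$feature, names(sort(-abs(tt)))[seq_len(40)])
})

test_that("moment-estimated variance shrinkage matches the limma oracle", {
  skip_if_not_installed("limma")
  x <- random_expr(300, 16, seed = 22)
  lab <- setNames(rep(c("A", "B"), 8), colnames(x))
  i1 <- lab == "A"; i2 <- lab == "B"
  s2 <- (7 * apply(x[, i1], 1, var) + 7 * apply(x[, i2], 1, var)) / 14
  sq <- limma::squeezeVar(s2, df = 14)
  res <- suppressWarnings(moderated_t_screen(x, lab, top_k = 300))
  d <- rowMeans(x[, i1]) - rowMeans(x[, i2])
  t_limma <- d / sqrt(sq$var.post * (2 / 8))
  expect_equal(res$statistic, unname(t_limma[res$feature]), tolerance = 1e-8)
})

test_that("a large planted shift is screened first and top_k clamps", {
  x <- random_expr(100, 24, seed = 23)
  lab <- setNames(rep(c("A", "B"), 12), colnames(x))
  x["g050", lab == "A"] <- x["g050", lab == "A"] + 10
  res <- moderated_t_screen(x, lab, top_k = 10)
  expect_identical(res$feature[1], "g050")
  expect_warning(res_all <- moderated_t_screen(x, lab, top_k = 1000),
                 "exceeds feature count")
  expect_equal(nrow(res_all), 100)
})

test_that("global-test ranking equals the squared-correlation oracle", {
  set.seed(24)
  n <- 40
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:5)))
  lab <- setNames(rep(c("A", "B"), n / 2), rownames(x))
  rk <- global_test_rank(x, lab)
  y <- as.numeric(lab == "B")
  r2 <- apply(x, 2, function(v) cor(v, y)^2)
  expect_identical(rk$feature, names(sort(-r2)))

  # constant feature scores zero and ranks last
  x2 <- cbind(x, konst = 1)
  rk2 <- global_test_rank(x2, lab)
  expect_equal(rk2$score[rk2$feature == "konst"], 0)
  expect_identical(rk2$feature[6], "konst")

  # a feature equal to the label indicator dominates equal-scale noise
  x3 <- cbind(scale(x), label_copy = as.numeric(scale(y)))
  rk3 <- global_test_rank(x3, lab)
  expect_identical(rk3$feature[1], "label_copy")
})

test_that("backward elimination walks nested prefixes down to 3", {
  set.seed(25)
  n <- 30
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:5)))
  lab <- setNames(rep(c("A", "Rest"), n / 2), rownames(x))
  x[lab == "A", "f1"] <- x[lab == "A", "f1"] + 6   # separable via f1
  rk <- global_test_rank(x, lab)
  be <- backward_elimination(x, x, lab, rk$feature, "A")
  expect_equal(be$trajectory$size, c(5, 4, 3))
  expect_true(all(be$trajectory$sensitivity == 1))  # separable at all sizes
  expect_equal(be$best_size, 3)                     # ties go to smaller size

  # degenerate inner test with one positive sample: sensitivity is 0 or 1
  xt <- x[c(1, 2, 4, 6), ]
  be2 <- backward_elimination(x, xt, lab, rk$feature, "A")
  expect_true(all(be2$trajectory$sensitivity %in% c(0, 1)))

  expect_error(backward_elimination(x, x, lab, c("f1", "f2"), "A"),
               "at least 3")
})

test_that("nested CV selection recovers planted features and is deterministic", {
  cfg <- sim_config(n_per_class = 36, n_background = 190, sets = list(),
                    n_planted = 10, test_fraction = 0)
  ds <- generate_dataset(cfg, seed = 31)
  m <- apply_preprocessing_variant(ds$expr, "V1")
  sig <- suppressWarnings(suppressMessages(
    nested_cv_select(m, class_name = "A", n_ocv = 2, n_icv = 2, seed = 17)))
  expect_s3_class(sig, "signature_list")
  expect_true(sig$size >= 3 && sig$size <= 50)
  # at this small scale sensitivity saturates and the size tie-break keeps
  # the list short; what matters is that the list is made of planted genes
  expect_gt(mean(sig$features %in% ds$truth$planted_genes), 0.75)

  # byte-identical output under the same master seed
  sig2 <- suppressWarnings(suppressMessages(
    nested_cv_select(m, class_name = "A", n_ocv = 2, n_icv = 2, seed = 17)))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, p1); write_signature(sig2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("validation samples never enter the selection machinery", {
  cfg <- sim_config(n_per_class = 24, n_background = 90, sets = list(),
                    n_planted = 6, test_fraction = 0)
  ds <- generate_dataset(cfg, seed = 32)
  m <- apply_preprocessing_variant(ds$expr, "V1")
  sv <- suppressWarnings(suppressMessages(
    select_and_validate(m, class_name = "A", n_ocv = 2, n_icv = 2, seed = 5)))
  prov <- sv$signature$provenance
  val <- prov$validation_ids
  expect_true(length(val) > 0)
  expect_length(intersect(val, prov$discovery_ids), 0)
  for (it in prov$ocv) {
    expect_length(intersect(val, c(it$train_ids, it$test_ids)), 0)
  }
})
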