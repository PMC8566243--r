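test_that("spatial correlation matches the closed-form Pearson coefficient", {
  x <- c(1, 2, 3)
  expect_equal(spatial_correlation(x, x), 1)
  expect_equal(spatial_correlation(x, -x + 10), -1)
  # r for (1,2,3) vs (1,2,4) by explicit arithmetic
  y <- c(1, 2, 4)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(spatial_correlation(x, y), r, tolerance = 1e-12)
  expect_equal(round(r, 5), 0.98198)

  expect_true(is.na(spatial_correlation(c(1, 1, 1), y)))   # zero variance
  expect_error(spatial_correlation(1:3, 1:4), "lengths differ")

  # invariance under positive affine transforms
  withr::local_seed(31)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(spatial_correlation(2.5 * a + 7, b),
               spatial_correlation(a, b), tolerance = 1e-12)
})

test_that("an injected perfect mapping scores 1 on every informative gene", {
  # scoring isolated from optimization: M fixed to the ground truth
  fx <- self_mapping_fixture(5, seed = 13)
  M <- matrix(0, 5, 5); M[cbind(fx$perm, 1:5)] <- 1
  res <- manual_mapping_result(M)
  pred <- project_genes(res, fx$S)$values
  for (k in seq_len(ncol(fx$G)))
    expect_equal(spatial_correlation(pred[, k], fx$G[, k]), 1,
                 tolerance = 1e-9)
})

test_that("leave-one-out fits once per gene and flags degenerate genes", {
  fx <- self_mapping_fixture(3, genes_per_cell = 2L, seed = 17)
  # last gene all-zero in both modalities
  sc <- sc_matrix(cbind(fx$S[, 1:5], 0), gene_ids = paste0("g", 1:6))
  sp <- spatial_matrix(cbind(fx$G[, 1:5], 0), gene_ids = paste0("g", 1:6))

  loo <- leave_one_out(sc, sp, fx$d, panel = c("g1", "g2"), epochs = 200,
                       seed = 0)
  expect_identical(nrow(loo), 2L)           # exactly one fit per panel gene
  expect_identical(loo$gene, c("g1", "g2"))

  loo0 <- leave_one_out(sc, sp, fx$d, panel = c("g1", "g6"), epochs = 50,
                        seed = 0)
  expect_true(is.na(loo0$score[loo0$gene == "g6"]))   # zero-variance holdout
  expect_equal(loo0$sparsity[loo0$gene == "g6"], 1)

  expect_error(leave_one_out(sc, sp, fx$d, panel = "g1"), ">= 2 genes")
})

test_that("leave-one-out recovers held-out structure on the identity fixture", {
  fx <- self_mapping_fixture(4, genes_per_cell = 3L, seed = 19)
  sc <- sc_matrix(fx$S, gene_ids = paste0("g", 1:12))
  sp <- spatial_matrix(fx$G, gene_ids = paste0("g", 1:12))
  loo <- leave_one_out(sc, sp, fx$d, panel = sc$gene_ids, epochs = 400,
                       seed = 0)
  expect_true(all(loo$score > 0.95))
})

test_that("train/test partition separates the panel from scoreable genes", {
  genes <- paste0("g", 1:10)
  part <- train_test_partition(genes, genes[1:3])
  expect_identical(part$train, genes[1:3])
  expect_identical(length(part$test), 7L)

  expect_warning(train_test_partition(genes, genes), "empty test")
  part2 <- train_test_partition(genes, genes[1:3],
                                sp_genes = c("g4", "g5", "zzz"))
  expect_identical(part2$test, c("g4", "g5"))
  expect_error(train_test_partition(genes[1:5], c("g1", "g9")), "absent")
})

test_that("training-fraction sweep is seeded and reproduces the base at 1.0", {
  suite <- standard_suite(seed = 1)
  sc <- suite$truth$sc
  panel <- sc$gene_ids[seq(1, 200, by = 10)]          # 20 genes
  d <- density_from_segmentation(suite$truth$seg_counts)
  sw <- training_fraction_sweep(sc, suite$sp, d, panel,
                                fractions = c(1, 0.5), seed = 3,
                                epochs = 150)
  base <- holdout_scores(sc, suite$sp, d, panel, epochs = 150, seed = 3)
  expect_equal(sw$mean_train_score[sw$fraction == 1],
               mean(base$score[base$train], na.rm = TRUE), tolerance = 1e-12)
  sw2 <- training_fraction_sweep(sc, suite$sp, d, panel,
                                 fractions = 0.5, seed = 3, epochs = 150)
  expect_equal(sw2$mean_test_score, sw$mean_test_score[sw$fraction == 0.5],
               tolerance = 1e-12)                     # same seed, same subsample
  expect_warning(
    training_fraction_sweep(sc, suite$sp, d, panel, fractions = 0.05,
                            seed = 3, epochs = 50), "skipped")
  expect_error(
    training_fraction_sweep(sc, suite$sp, d, panel, fractions = 1.5,
                            seed = 3), "\\(0, 1\\]")
})

test_that("score quantiles and sparsity regions follow their definitions", {
  tab <- data.frame(gene = paste0("g", 1:10),
                    score = seq(0.1, 1, by = 0.1),
                    train = rep(TRUE, 10),
                    sparsity = rep(0, 10),
                    prediction_sparsity = 0)
  q <- score_quantiles(tab, 0.9, subset = "train")
  expect_gte(q, 0.9); expect_lte(q, 1.0)
  expect_error(score_quantiles(tab, 0.9, subset = "test"), "no scores")

  expect_equal(
    sparsity_stratified_summary(tab, threshold = 0.55),
    c(nonsparse_above = 5L, nonsparse_below = 5L, sparse = 0L))
  expect_equal(unname(sparsity_stratified_summary(tab, threshold = 2)[1]), 0L)
  tab$sparsity <- c(rep(0.9, 4), rep(0, 6))
  expect_equal(unname(sparsity_stratified_summary(tab, 0.5)["sparse"]), 4L)
})
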