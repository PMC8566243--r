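test_that("annotation transfer is the exact matrix product", {
  # identity mapping: annotations pass through unchanged
  A <- annotation_table(matrix(runif(6), 3, 2), c("a1", "a2"),
                        paste0("c", 1:3))
  res <- manual_mapping_result(diag(3), cell_ids = paste0("c", 1:3),
                               voxel_ids = paste0("v", 1:3))
  out <- project_annotations(res, A)
  expect_equal(unname(out$values), unname(A$values))

  # one-hot transfer without filter conserves per-type totals
  withr::local_seed(21)
  M <- softmax_rows(matrix(rnorm(40), 8, 5))
  labels <- sample(c("A", "B", "C"), 8, replace = TRUE)
  res2 <- manual_mapping_result(M)
  out2 <- project_annotations(res2, one_hot_labels(labels))
  expect_equal(colSums(out2$values), c(table(labels)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # an all-ones filter equals no filter
  res3 <- manual_mapping_result(M, f = rep(1, 8))
  out3 <- project_annotations(res3, one_hot_labels(labels), use_filter = TRUE)
  expect_equal(out3$values, out2$values)

  # misaligned cell ids
  resn <- manual_mapping_result(diag(3), cell_ids = paste0("x", 1:3))
  expect_error(project_annotations(resn, A), "do not match")
})

test_that("gene projection imputes held-out genes and is linear", {
  # permutation mapping on a self-mapping fixture reproduces G up to scale
  fx <- self_mapping_fixture(4, seed = 9)
  M <- matrix(0, 4, 4); M[cbind(fx$perm, 1:4)] <- 1
  res <- manual_mapping_result(M)
  pred <- project_genes(res, fx$S)
  expect_equal(unname(pred$values), unname(fx$G), tolerance = 1e-12)

  # all-zero gene stays all-zero
  S0 <- cbind(fx$S, zero = 0)
  expect_equal(unname(project_genes(res, S0)$values[, ncol(S0)]), rep(0, 4))

  # linearity in S_full
  withr::local_seed(22)
  Mr <- softmax_rows(matrix(rnorm(12), 4, 3))
  resr <- manual_mapping_result(Mr)
  S1 <- matrix(runif(8), 4, 2); S2 <- matrix(runif(8), 4, 2)
  expect_equal(project_genes(resr, S1 + S2)$values,
               project_genes(resr, S1)$values +
                 project_genes(resr, S2)$values, tolerance = 1e-12)
})

test_that("a type-specific unseen gene concentrates where its type maps", {
  # two cell types in two spatial halves; an extra gene only in type B cells
  S_train <- rbind(c(4, 0.1), c(4, 0.1), c(0.1, 4), c(0.1, 4))
  G <- rbind(c(4, 0.1), c(0.1, 4))          # voxel 1 = type A, voxel 2 = B
  fit <- fit_mapping(S_train, G, uniform_density(2), epochs = 300, seed = 0)
  unseen <- c(0, 0, 5, 5)                   # expressed only in type B cells
  pred <- project_genes(fit, cbind(S_train, unseen = unseen))
  expect_gt(pred$values[2, "unseen"], pred$values[1, "unseen"] * 5)
})

test_that("deterministic cell-type calling honors both rules", {
  labels <- c("A", "B", "C")
  res <- manual_mapping_result(diag(3))
  expect_equal(unname(deterministic_celltype_map(res, labels)), labels)
  expect_equal(unname(deterministic_celltype_map(res, labels,
                                                 method = "cell")), labels)

  # argmax-cell ties break to the lowest cell index
  M <- rbind(c(0.5, 0.2), c(0.5, 0.2), c(0, 0.6))
  res2 <- manual_mapping_result(M)
  expect_identical(unname(deterministic_celltype_map(res2, labels,
                                                     method = "cell")[1]), "A")

  # every cell filtered out -> unassigned voxels
  res3 <- manual_mapping_result(diag(3), f = rep(0.1, 3))
  expect_true(all(is.na(deterministic_celltype_map(res3, labels,
                                                   method = "cell"))))

  # on a mixed spot, type_mass follows the aggregate, not the top cell
  Mmix <- matrix(c(0.35, 0.34, 0.31), 3, 1)   # two B cells outweigh one A
  res4 <- manual_mapping_result(Mmix)
  expect_identical(unname(deterministic_celltype_map(
    res4, c("A", "B", "B"), method = "type_mass")), "B")
  expect_identical(unname(deterministic_celltype_map(
    res4, c("A", "B", "B"), method = "cell")), "A")
})

test_that("deconvolution matches cells to segmented cells without reuse", {
  # 1 voxel, 2 segmented cells, 2 filtered cells mapped there
  M <- matrix(1, 2, 1)
  res <- manual_mapping_result(M, f = c(0.9, 0.8),
                               cell_ids = c("c1", "c2"), voxel_ids = "v1")
  out <- deconvolve(res, c("A", "B"), seg_counts = 2, seed = 1)
  expect_identical(nrow(out$assignments), 2L)
  expect_setequal(out$assignments$cell_id, c("c1", "c2"))
  expect_identical(anyDuplicated(out$assignments$cell_id), 0L)

  # determinism under the same seed
  out2 <- deconvolve(res, c("A", "B"), seg_counts = 2, seed = 1)
  expect_identical(out$assignments, out2$assignments)

  # 3 segmented, 1 mapped -> 2 unassigned slots
  res3 <- manual_mapping_result(matrix(1, 1, 1), f = 0.9,
                                cell_ids = "c1", voxel_ids = "v1")
  out3 <- deconvolve(res3, "A", seg_counts = 3, seed = 0)
  expect_identical(sum(is.na(out3$assignments$cell_id)), 2L)

  # surplus mapped cells are reported unplaced with a warning
  res4 <- manual_mapping_result(matrix(1, 3, 1), f = rep(0.9, 3),
                                cell_ids = paste0("c", 1:3), voxel_ids = "v1")
  expect_warning(out4 <- deconvolve(res4, c("A", "B", "C"), seg_counts = 1,
                                    seed = 0), "unplaced")
  expect_identical(length(out4$unplaced_cells), 2L)

  # plain-mode result has no filter
  expect_error(deconvolve(manual_mapping_result(M), c("A", "B"), 2),
               "filter")
})
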