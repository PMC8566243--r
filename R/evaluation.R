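# Holdout-gene validation: a gene left out of the training panel is imputed
# from the learned mapping and scored against its measured spatial pattern.
# Drivers: leave-one-out over a panel, a single train/test partition over the
# whole shared gene set, and a training-fraction sweep.

#' Spatial correlation between a predicted and a measured gene pattern
#'
#' Pearson correlation across voxels between the imputed and the measured
#' per-voxel expression of one gene. Undefined (NA) when either vector is
#' constant. Spearman is available for rank-based scoring.
#'
#' @param pred,meas Numeric per-voxel vectors of equal length (>= 2).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation in \[-1, 1\], or NA when undefined.
#' @export
spatial_correlation <- function(pred, meas, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  pred <- as.numeric(pred); meas <- as.numeric(meas)
  if (length(pred) != length(meas))
    stop("prediction and measurement lengths differ", call. = FALSE)
  if (length(pred) < 2L) stop("need at least 2 voxels", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(meas) == 0) return(NA_real_)
  stats::cor(pred, meas, method = method)
}

# Score every column of a predicted matrix against the measured spatial
# matrix; returns a GeneScoreTable-style data.frame.
.score_genes <- function(pred_vals, sp, genes, train_flag, method = "pearson") {
  sparsity <- colMeans(sp$values[, genes, drop = FALSE] == 0)
  pred_sparsity <- colMeans(pred_vals[, genes, drop = FALSE] == 0)
  score <- vapply(genes, function(g)
    spatial_correlation(pred_vals[, g], sp$values[, g], method = method),
    numeric(1))
  data.frame(gene = genes, score = score, train = train_flag,
             sparsity = as.numeric(sparsity),
             prediction_sparsity = as.numeric(pred_sparsity),
             row.names = NULL)
}

#' Leave-one-out holdout validation over a gene panel
#'
#' For every gene in the panel the model is refitted on the remaining panel
#' genes (same init seed per fold for comparability), the held-out gene is
#' imputed via [project_genes()], and its spatial correlation with the
#' measurement is recorded.
#'
#' @param sc An `sc_matrix` (genes must cover the panel).
#' @param sp A `spatial_matrix` (genes must cover the panel).
#' @param d Density prior.
#' @param panel Character vector of >= 2 gene ids.
#' @param mode,n_target_cells,epochs,lr,seed,weights,lambda_r1 Passed to
#'   [fit_mapping()].
#' @param method Correlation method, see [spatial_correlation()].
#' @return A data.frame (GeneScoreTable): gene, score, train flag (all FALSE:
#'   each scored gene was held out), sparsity, prediction sparsity.
#' @export
leave_one_out <- function(sc, sp, d, panel, mode = "plain",
                          n_target_cells = NULL, epochs = 300L, lr = 0.1,
                          seed = 0L, weights = c(1, 1, 1), lambda_r1 = 0,
                          method = "pearson") {
  panel <- as.character(panel)
  if (length(panel) < 2L) stop("leave-one-out needs a panel of >= 2 genes", call. = FALSE)
  aligned <- intersect_genes(sc, sp, panel)
  panel <- aligned$genes
  rows <- lapply(panel, function(g) {
    train_genes <- setdiff(panel, g)
    fit <- tryCatch(
      fit_mapping(aligned$sc$values[, train_genes, drop = FALSE],
                  aligned$sp$values[, train_genes, drop = FALSE],
                  d, mode = mode, n_target_cells = n_target_cells,
                  epochs = epochs, lr = lr, seed = seed, weights = weights,
                  lambda_r1 = lambda_r1),
      error = function(e) stop("leave-one-out fit failed for held-out gene ",
                               g, ": ", conditionMessage(e), call. = FALSE))
    pred <- crossprod(fit$M, if (is.null(fit$f)) aligned$sc$values[, g]
                      else fit$f * aligned$sc$values[, g])
    meas <- aligned$sp$values[, g]
    data.frame(gene = g,
               score = spatial_correlation(pred, meas, method = method),
               train = FALSE,
               sparsity = mean(meas == 0),
               prediction_sparsity = mean(pred == 0), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Train/test gene partition
#'
#' Training genes are the panel; test genes are all remaining single-cell
#' genes, restricted to those also measured spatially (only those can be
#' scored).
#'
#' @param all_genes Character vector of single-cell gene ids.
#' @param panel Training panel (subset of `all_genes`).
#' @param sp_genes Optional spatial gene ids used to restrict the test set.
#' @return List with `train` and `test` character vectors.
#' @export
train_test_partition <- function(all_genes, panel, sp_genes = NULL) {
  all_genes <- as.character(all_genes); panel <- as.character(panel)
  if (!all(panel %in% all_genes))
    stop("panel contains genes absent from all_genes", call. = FALSE)
  test <- setdiff(all_genes, panel)
  if (!is.null(sp_genes)) test <- intersect(test, as.character(sp_genes))
  if (length(test) == 0L)
    warning("empty test set: the panel covers every scoreable gene", call. = FALSE)
  list(train = panel, test = test)
}

#' Fit once and score the train/test gene partition
#'
#' Fits the mapping on the training panel, imputes every shared gene, and
#' scores train and test genes separately.
#'
#' @inheritParams leave_one_out
#' @return A GeneScoreTable data.frame over train + test genes.
#' @export
holdout_scores <- function(sc, sp, d, panel, mode = "plain",
                           n_target_cells = NULL, epochs = 300L, lr = 0.1,
                           seed = 0L, weights = c(1, 1, 1), lambda_r1 = 0,
                           method = "pearson") {
  shared <- intersect_genes(sc, sp)
  panel <- intersect(as.character(panel), shared$genes)
  if (length(panel) < 2L) stop("training panel too small after intersection", call. = FALSE)
  part <- train_test_partition(shared$genes, panel, shared$genes)
  fit <- fit_mapping(shared$sc$values[, panel, drop = FALSE],
                     shared$sp$values[, panel, drop = FALSE],
                     d, mode = mode, n_target_cells = n_target_cells,
                     epochs = epochs, lr = lr, seed = seed, weights = weights,
                     lambda_r1 = lambda_r1)
  pred <- crossprod(fit$M, if (is.null(fit$f)) shared$sc$values
                    else fit$f * shared$sc$values)
  colnames(pred) <- shared$genes
  rbind(
    .score_genes(pred, shared$sp, part$train, TRUE, method),
    if (length(part$test))
      .score_genes(pred, shared$sp, part$test, FALSE, method)
  )
}

#' Training-fraction sweep
#'
#' Subsamples the training panel at each fraction (uniformly, seeded), refits,
#' and scores the fixed test set; reports mean train score, mean test score
#' and the test score scaled by the mean training-gene score.
#'
#' @inheritParams leave_one_out
#' @param fractions Numeric vector in (0, 1\].
#' @return A data.frame with one row per fraction: `fraction`,
#'   `n_train_genes`, `mean_train_score`, `mean_test_score`,
#'   `scaled_test_score`.
#' @export
training_fraction_sweep <- function(sc, sp, d, panel, fractions, seed = 0L,
                                    mode = "plain", n_target_cells = NULL,
                                    epochs = 300L, lr = 0.1,
                                    weights = c(1, 1, 1), lambda_r1 = 0,
                                    method = "pearson") {
  panel <- as.character(panel)
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  rows <- lapply(fractions, function(fr) {
    n_keep <- max(0L, round(fr * length(panel)))
    if (n_keep < 2L) {
      warning(sprintf("fraction %.3g keeps %d genes (< 2); skipped", fr, n_keep),
              call. = FALSE)
      return(NULL)
    }
    sub <- if (n_keep == length(panel)) panel else
      .with_seed(seed, sort(sample(panel, n_keep)))
    tab <- holdout_scores(sc, sp, d, sub, mode = mode,
                          n_target_cells = n_target_cells, epochs = epochs,
                          lr = lr, seed = seed, weights = weights,
                          lambda_r1 = lambda_r1, method = method)
    tr <- mean(tab$score[tab$train], na.rm = TRUE)
    te <- mean(tab$score[!tab$train], na.rm = TRUE)
    data.frame(fraction = fr, n_train_genes = n_keep, mean_train_score = tr,
               mean_test_score = te, scaled_test_score = te / tr,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Empirical quantile of gene scores
#'
#' @param table A GeneScoreTable data.frame.
#' @param q Quantile in \[0, 1\] (e.g. 0.9 for the 90th percentile).
#' @param subset `"train"`, `"test"` or `"all"`.
#' @return Scalar quantile (linear-interpolation estimator, type 7).
#' @export
score_quantiles <- function(table, q = 0.9, subset = c("all", "train", "test")) {
  subset <- match.arg(subset)
  s <- switch(subset, all = table$score,
              train = table$score[table$train],
              test = table$score[!table$train])
  s <- s[!is.na(s)]
  if (length(s) == 0L) stop("no scores in the requested subset", call. = FALSE)
  unname(stats::quantile(s, q, type = 7))
}

#' Stratify gene scores by sparsity and performance
#'
#' Partitions genes into three regions: (i) non-sparse (sparsity < 0.5) and
#' scoring at or above the threshold, (ii) non-sparse scoring below it, and
#' (iii) sparse (sparsity >= 0.5). Undetected-in-prediction genes with NA
#' scores fall in their sparsity region with the below-threshold group.
#'
#' @param table A GeneScoreTable data.frame.
#' @param threshold Score threshold separating regions (i) and (ii).
#' @return Named integer vector with counts `nonsparse_above`,
#'   `nonsparse_below`, `sparse`.
#' @export
sparsity_stratified_summary <- function(table, threshold) {
  if (nrow(table) == 0L) stop("empty score table", call. = FALSE)
  sparse <- table$sparsity >= 0.5
  above <- !is.na(table$score) & table$score >= threshold
  c(nonsparse_above = sum(!sparse & above),
    nonsparse_below = sum(!sparse & !above),
    sparse = sum(sparse))
}
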