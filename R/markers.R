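# Training-panel selection: per-type differential expression by Welch t-test.
#
# Mapping does not use the whole transcriptome: low-quality and non-marker
# genes fluctuate in their basal signal and would not contribute. The panel
# is the union of the top-k one-vs-rest marker genes of every cell type,
# intersected with the genes measured in the spatial data; all other shared
# genes become held-out test genes for imputation scoring.

#' Standard single-cell preprocessing for marker selection
#'
#' Library-size normalization, log(1 + x) transform, then per-gene
#' standardization (z-score across cells). This is the scale on which the
#' marker t-statistics are computed; the matrices handed to the mapper itself
#' stay on the library-normalized (linear) scale.
#'
#' @param sc An `sc_matrix` of raw counts.
#' @param target_sum Library-size target, default 1e4.
#' @return An `sc_matrix` with standardized values (genes with zero variance
#'   are left at 0).
#' @export
preprocess_for_markers <- function(sc, target_sum = 1e4) {
  sc <- log1p_transform(normalize_library_size(sc, target_sum))
  mu <- colMeans(sc$values)
  sdv <- apply(sc$values, 2L, stats::sd)
  sdv[sdv == 0] <- 1   # constant genes stay at zero after centering
  sc$values <- sweep(sweep(sc$values, 2L, mu, "-"), 2L, sdv, "/")
  # standardized values may be negative; bypass the non-negativity check
  out <- unclass(sc)
  structure(out, class = c("sc_matrix_standardized", "list"))
}

#' Rank marker genes per cell type (one-vs-rest Welch t-test)
#'
#' For every cell-type label, computes the Welch (unequal-variance)
#' two-sample t statistic of that type's cells against all remaining cells,
#' gene by gene, and ranks genes by descending signed statistic so that
#' upregulated markers come first. Ties are broken lexicographically by gene
#' id. Expression should already be library-normalized, log-transformed and
#' per-gene standardized (see [preprocess_for_markers()]).
#'
#' @param sc An `sc_matrix` (or the output of [preprocess_for_markers()])
#'   with per-cell `labels`; every label needs at least 2 cells.
#' @param labels Optional label vector overriding `sc$labels`.
#' @return A list of class `marker_ranking`: per type, a data.frame with
#'   columns `gene`, `statistic`, `rank` sorted by descending statistic.
#' @export
rank_markers <- function(sc, labels = sc$labels) {
  X <- sc$values
  if (is.null(labels)) stop("cell-type labels are required", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("labels length != number of cells", call. = FALSE)
  types <- sort(unique(labels))
  if (length(types) < 2L) stop("need at least 2 cell types", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every type needs >= 2 cells; too small: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)

  genes <- colnames(X)
  per_type <- lapply(types, function(ty) {
    in_grp <- labels == ty
    n1 <- sum(in_grp); n2 <- sum(!in_grp)
    X1 <- X[in_grp, , drop = FALSE]; X2 <- X[!in_grp, , drop = FALSE]
    m1 <- colMeans(X1); m2 <- colMeans(X2)
    v1 <- colSums(sweep(X1, 2L, m1, "-")^2) / (n1 - 1L)
    v2 <- colSums(sweep(X2, 2L, m2, "-")^2) / (n2 - 1L)
    se <- sqrt(v1 / n1 + v2 / n2)
    stat <- ifelse(se > 0, (m1 - m2) / se,
                   ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
    ord <- order(-stat, genes)
    data.frame(gene = genes[ord], statistic = stat[ord],
               rank = seq_along(genes), row.names = NULL)
  })
  names(per_type) <- types
  structure(per_type, class = "marker_ranking")
}

#' @export
print.marker_ranking <- function(x, n = 3L, ...) {
  cat(sprintf("marker_ranking: %d types\n", length(x)))
  for (ty in names(x))
    cat(sprintf("  %s: %s ...\n", ty,
                paste(utils::head(x[[ty]]$gene, n), collapse = ", ")))
  invisible(x)
}

#' Training panel from a marker ranking
#'
#' The union of each type's top-`k` marker genes, intersected with the genes
#' measured in the spatial data. Order is deterministic: types in ranking
#' order, genes by rank within type, duplicates kept at first appearance.
#'
#' @param ranking A `marker_ranking`.
#' @param k Markers per type; default 100.
#' @param sp Optional `spatial_matrix` (or character vector of gene ids) to
#'   intersect the panel with.
#' @return Character vector of gene ids.
#' @export
training_panel <- function(ranking, k = 100L, sp = NULL) {
  stopifnot(inherits(ranking, "marker_ranking"), k >= 1L)
  picked <- unlist(lapply(ranking, function(df) utils::head(df$gene, k)),
                   use.names = FALSE)
  panel <- picked[!duplicated(picked)]
  if (!is.null(sp)) {
    sp_genes <- if (inherits(sp, "spatial_matrix")) sp$gene_ids else as.character(sp)
    panel <- panel[panel %in% sp_genes]
  }
  if (length(panel) == 0L)
    stop("training panel is empty after intersection with spatial genes",
         call. = FALSE)
  panel
}
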