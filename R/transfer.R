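# Using a learned mapping: projecting annotations and genes into space,
# deterministic cell-type calling, and spot deconvolution.

#' Transfer per-cell annotations into space
#'
#' Computes `t(M) %*% A` (or `t(M) %*% (f * A)` when the learned filter is
#' applied): the annotation content of every voxel implied by the mapping.
#' With one-hot cell-type annotations this yields the probabilistic count of
#' every type in every voxel; without a filter those probabilistic counts
#' conserve the per-type totals exactly because rows of `M` sum to 1.
#'
#' @param result A `mapping_result`.
#' @param A An `annotation_table` (rows aligned with the mapped cells) or a
#'   plain cells x annotations matrix.
#' @param use_filter Apply the learned filter `f` when present; default TRUE.
#' @return A list of class `spatial_projection` with `values` (voxels x
#'   annotations), `voxel_ids`, `annotation_ids` and `filtered` flag.
#' @export
project_annotations <- function(result, A, use_filter = TRUE) {
  stopifnot(inherits(result, "mapping_result"))
  ann_ids <- NULL
  if (inherits(A, "annotation_table")) {
    if (!is.null(result$cell_ids) && !identical(A$cell_ids, result$cell_ids))
      stop("annotation cell ids do not match the mapping's cells", call. = FALSE)
    ann_ids <- A$annotation_ids
    A <- A$values
  }
  A <- as.matrix(A)
  if (nrow(A) != nrow(result$M))
    stop("annotation rows must match mapped cells", call. = FALSE)
  filt <- use_filter && !is.null(result$f)
  vals <- crossprod(result$M, if (filt) result$f * A else A)
  rownames(vals) <- result$voxel_ids
  if (!is.null(ann_ids)) colnames(vals) <- ann_ids
  structure(list(values = vals, voxel_ids = result$voxel_ids,
                 annotation_ids = colnames(vals), filtered = filt),
            class = "spatial_projection")
}

#' Predict genome-wide spatial expression
#'
#' Projects the full single-cell expression matrix through the mapping:
#' `t(M) %*% S_full` (filter-weighted when requested). Genes never used in
#' training are imputed from the spatial arrangement of the cells that
#' express them — this is the surface on which held-out genes are scored.
#'
#' @param result A `mapping_result`.
#' @param S_full An `sc_matrix` (or matrix) covering the mapped cells; may
#'   contain any genes, including ones absent from the training panel.
#' @param use_filter Apply the learned filter when present; default TRUE.
#' @return A `spatial_projection` with one column per gene of `S_full`.
#' @export
project_genes <- function(result, S_full, use_filter = TRUE) {
  gene_ids <- NULL
  if (inherits(S_full, "sc_matrix")) {
    if (!is.null(result$cell_ids) && !identical(S_full$cell_ids, result$cell_ids))
      stop("single-cell ids do not match the mapping's cells", call. = FALSE)
    gene_ids <- S_full$gene_ids
    S_full <- S_full$values
  }
  S_full <- as.matrix(S_full)
  if (nrow(S_full) != nrow(result$M))
    stop("S_full rows must match mapped cells", call. = FALSE)
  filt <- use_filter && !is.null(result$f)
  vals <- crossprod(result$M, if (filt) result$f * S_full else S_full)
  rownames(vals) <- result$voxel_ids
  if (!is.null(gene_ids)) colnames(vals) <- gene_ids
  structure(list(values = vals, voxel_ids = result$voxel_ids,
                 annotation_ids = colnames(vals), filtered = filt),
            class = "spatial_projection")
}

#' @export
print.spatial_projection <- function(x, ...) {
  cat(sprintf("spatial_projection: %d voxels x %d annotations%s\n",
              nrow(x$values), ncol(x$values),
              if (x$filtered) " (filter applied)" else ""))
  invisible(x)
}

#' Deterministic cell-type calling
#'
#' Assigns one cell-type label to every voxel. The default `"type_mass"`
#' method transfers the one-hot cell-type annotations into space and takes,
#' per voxel, the type with the largest probabilistic count — the most likely
#' type under the voxel's (unnormalized) type distribution. The `"cell"`
#' method instead takes the label of the single highest-probability cell
#' (`argmax_i M[i, j]`, ties to the lowest cell index). The two agree on
#' sharply converged single-cell-resolution mappings; on multi-cell spots
#' only `"type_mass"` reflects the spot's composition.
#'
#' @param result A `mapping_result`.
#' @param labels Per-cell label vector aligned with the mapped cells.
#' @param method `"type_mass"` (default) or `"cell"`.
#' @param filter_threshold For `"cell"` with a learned filter: cells with `f`
#'   at or below this value are excluded (default 0.5); `"type_mass"`
#'   weights cells by `f` instead. A voxel left with no signal is NA.
#' @return Character vector of per-voxel labels (NA where unassigned), named
#'   by voxel id when available.
#' @export
deterministic_celltype_map <- function(result, labels,
                                       method = c("type_mass", "cell"),
                                       filter_threshold = 0.5) {
  stopifnot(inherits(result, "mapping_result"))
  method <- match.arg(method)
  labels <- as.character(labels)
  if (length(labels) != nrow(result$M))
    stop("labels length must match mapped cells", call. = FALSE)
  M <- result$M
  out <- rep(NA_character_, ncol(M))
  if (method == "type_mass") {
    A <- one_hot_labels(labels)
    mass <- crossprod(M, if (is.null(result$f)) A$values else result$f * A$values)
    live <- rowSums(mass) > 0
    out[live] <- A$annotation_ids[apply(mass[live, , drop = FALSE], 1L, which.max)]
  } else {
    keep <- if (is.null(result$f)) rep(TRUE, nrow(M)) else
      result$f > filter_threshold
    if (any(keep)) {
      sub <- M[keep, , drop = FALSE]
      best <- apply(sub, 2L, which.max)   # first maximum = lowest index tie-break
      out <- labels[keep][best]
    }
  }
  names(out) <- result$voxel_ids
  out
}

#' Deconvolve spots into individually typed segmented cells
#'
#' Places every filter-retained cell (`f > 0.5`) in its highest-probability
#' voxel, then matches placed cells to that voxel's segmented cells uniformly
#' at random under the given seed. Segmented cells left without a mapped cell
#' are flagged unassigned; if more cells land in a voxel than it has
#' segmented cells, the surplus is reported unplaced with a warning.
#'
#' @param result A filtered-mode `mapping_result` (requires `f`).
#' @param labels Per-cell labels aligned with the mapped cells.
#' @param seg_counts Per-voxel segmented cell counts.
#' @param seed Seed for the within-voxel random matching (independent of the
#'   mapping seed).
#' @return A list of class `deconvolution_assignment` with `assignments`
#'   (data.frame: voxel_id, segmented_cell_index, cell_id, label; NA cell for
#'   unassigned segmented cells) and `unplaced_cells` (cell ids that exceeded
#'   their voxel's segmented count).
#' @export
deconvolve <- function(result, labels, seg_counts, seed = 0L) {
  stopifnot(inherits(result, "mapping_result"))
  if (is.null(result$f))
    stop("deconvolution requires a filtered-mode mapping (no filter learned)",
         call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(result$M))
    stop("labels length must match mapped cells", call. = FALSE)
  seg_counts <- as.integer(seg_counts)
  n_voxels <- ncol(result$M)
  if (length(seg_counts) != n_voxels)
    stop("seg_counts length must equal number of voxels", call. = FALSE)
  voxel_ids <- result$voxel_ids %||% paste0("voxel_", seq_len(n_voxels))
  cell_ids <- result$cell_ids %||% paste0("cell_", seq_len(nrow(result$M)))

  mapped <- which(result$f > 0.5)
  target_voxel <- if (length(mapped))
    apply(result$M[mapped, , drop = FALSE], 1L, which.max) else integer(0)

  rows <- vector("list", n_voxels)
  unplaced <- character(0)
  .with_seed(seed, {
    for (j in seq_len(n_voxels)) {
      here <- mapped[target_voxel == j]
      n_seg <- seg_counts[j]
      if (length(here) > n_seg) {
        # keep the most confidently mapped cells, report the surplus
        ord <- order(-result$M[here, j])
        drop_cells <- here[ord][-seq_len(n_seg)]
        unplaced <- c(unplaced, cell_ids[drop_cells])
        here <- here[ord][seq_len(n_seg)]
      }
      if (n_seg == 0L) { rows[[j]] <- NULL; next }
      slot <- sample(n_seg, length(here))   # random matching to segmented cells
      assigned_cell <- rep(NA_character_, n_seg)
      assigned_label <- rep(NA_character_, n_seg)
      if (length(here)) {
        assigned_cell[slot] <- cell_ids[here]
        assigned_label[slot] <- labels[here]
      }
      rows[[j]] <- data.frame(voxel_id = voxel_ids[j],
                              segmented_cell_index = seq_len(n_seg),
                              cell_id = assigned_cell, label = assigned_label,
                              row.names = NULL)
    }
  })
  if (length(unplaced))
    warning(length(unplaced),
            " mapped cell(s) exceeded their voxel's segmented count and were",
            " left unplaced", call. = FALSE)
  structure(list(assignments = do.call(rbind, rows),
                 unplaced_cells = unplaced, seed = seed),
            class = "deconvolution_assignment")
}

#' @export
print.deconvolution_assignment <- function(x, ...) {
  a <- x$assignments
  cat(sprintf("deconvolution: %d segmented cells, %d assigned, %d unassigned, %d unplaced sc cells\n",
              nrow(a), sum(!is.na(a$cell_id)), sum(is.na(a$cell_id)),
              length(x$unplaced_cells)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
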