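# Containers and validators for the cell-to-voxel mapping problem.
#
# The mapping problem involves four objects:
#   S  -- cells x genes single-cell expression (sc_matrix)
#   G  -- voxels x genes spatial expression   (spatial_matrix)
#   d  -- per-voxel expected cell density, a probability simplex (density_prior)
#   A  -- cells x annotations numeric matrix  (annotation_table)
# All expression values are non-negative reals in arbitrary units; the two
# modalities are never assumed to share a unit of measure.

.check_ids <- function(ids, what) {
  if (!is.character(ids)) ids <- as.character(ids)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop(what, " contains missing or empty ids", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate ", what, ": ",
         paste(unique(ids[duplicated(ids)])[seq_len(min(3, sum(duplicated(ids))))],
               collapse = ", "), call. = FALSE)
  ids
}

.check_values <- function(values, what) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(values) == 0L) stop(what, " matrix is empty", call. = FALSE)
  if (any(!is.finite(values))) stop(what, " matrix has non-finite entries", call. = FALSE)
  if (any(values < 0)) stop(what, " matrix has negative entries", call. = FALSE)
  values
}

#' Single-cell expression matrix
#'
#' Container for a cells x genes non-negative expression matrix with unique
#' cell and gene identifiers and optional per-cell type labels.
#'
#' @param values Numeric matrix, cells in rows, genes in columns. Entries must
#'   be finite and non-negative; units are arbitrary (raw or normalized
#'   counts).
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   the row names of `values`).
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   the column names of `values`).
#' @param labels Optional per-cell categorical labels (cell types), length
#'   equal to the number of cells.
#' @return An object of class `sc_matrix` with elements `values`, `cell_ids`,
#'   `gene_ids`, `labels`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' sc <- sc_matrix(m, labels = c("A", "A", "B"))
sc_matrix <- function(values, cell_ids = rownames(values),
                      gene_ids = colnames(values), labels = NULL) {
  values <- .check_values(values, "single-cell")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  cell_ids <- .check_ids(cell_ids, "cell_ids")
  gene_ids <- .check_ids(gene_ids, "gene_ids")
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values))
      stop("labels length (", length(labels), ") != number of cells (",
           nrow(values), ")", call. = FALSE)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 labels = labels),
            class = "sc_matrix")
}

#' Spatial expression matrix
#'
#' Container for a voxels x genes non-negative expression matrix. A voxel is
#' one spatial measurement unit: a segmented cell for targeted in situ data
#' (one cell per voxel) or a barcoded capture spot for array-based spatial
#' transcriptomics (several cells per voxel).
#'
#' @param values Numeric matrix, voxels in rows, genes in columns;
#'   non-negative and finite.
#' @param voxel_ids,gene_ids Unique identifier vectors (default to dimnames).
#' @param coords Optional voxels x 2 numeric matrix of spatial coordinates,
#'   used only for plotting/export.
#' @return An object of class `spatial_matrix`.
#' @export
spatial_matrix <- function(values, voxel_ids = rownames(values),
                           gene_ids = colnames(values), coords = NULL) {
  values <- .check_values(values, "spatial")
  if (is.null(voxel_ids)) voxel_ids <- paste0("voxel_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  voxel_ids <- .check_ids(voxel_ids, "voxel_ids")
  gene_ids <- .check_ids(gene_ids, "gene_ids")
  if (length(voxel_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != nrow(values) || ncol(coords) != 2L)
      stop("coords must be a voxels x 2 matrix", call. = FALSE)
  }
  dimnames(values) <- list(voxel_ids, gene_ids)
  structure(list(values = values, voxel_ids = voxel_ids, gene_ids = gene_ids,
                 coords = coords),
            class = "spatial_matrix")
}

#' Per-voxel cell-density prior
#'
#' A probability simplex over voxels: `d[j]` is the expected fraction of all
#' mapped cells that fall in voxel `j`.
#'
#' @param d Numeric vector with entries in \[0, 1\] summing to 1 (tolerance
#'   1e-9).
#' @return An object of class `density_prior` (a numeric vector).
#' @export
density_prior <- function(d) {
  d <- as.numeric(d)
  if (length(d) < 1L) stop("density prior is empty", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1))
    stop("density entries must lie in [0, 1]", call. = FALSE)
  if (abs(sum(d) - 1) > 1e-9)
    stop("density prior must sum to 1 (got ", format(sum(d), digits = 12), ")",
         call. = FALSE)
  structure(d, class = "density_prior")
}

#' Uniform density prior
#'
#' The expected density for single-cell-resolution spatial data, where each
#' voxel holds exactly one cell: `d[j] = 1 / n_voxels`.
#'
#' @param n_voxels Number of voxels (>= 1).
#' @return A `density_prior` of length `n_voxels`.
#' @export
uniform_density <- function(n_voxels) {
  if (!is.numeric(n_voxels) || length(n_voxels) != 1L || n_voxels < 1)
    stop("n_voxels must be a positive integer", call. = FALSE)
  density_prior(rep(1 / n_voxels, n_voxels))
}

#' Density prior from segmented cell counts
#'
#' Converts per-voxel segmented-cell counts (e.g. from nuclear segmentation of
#' the histology image under each capture spot) into a density prior by
#' normalizing to the simplex.
#'
#' @param counts Non-negative integer vector of segmented cells per voxel;
#'   the total must be positive.
#' @return A `density_prior` with `d[j] = counts[j] / sum(counts)`.
#' @export
density_from_segmentation <- function(counts) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("segmented counts must be non-negative and finite", call. = FALSE)
  tot <- sum(counts)
  if (tot <= 0) stop("segmented counts are all zero", call. = FALSE)
  density_prior(counts / tot)
}

#' Per-cell annotation table
#'
#' Any per-cell quantity to be transferred into space: one-hot encoded cell
#' types, ATAC peak counts, motif z-scores, or genes themselves.
#'
#' @param values Numeric cells x annotations matrix with finite entries.
#' @param annotation_ids Unique annotation identifiers (default column names).
#' @param cell_ids Unique cell identifiers (default row names).
#' @param encoding Either `"numeric"` or `"one-hot-categorical"`; in the
#'   latter case each row must sum to 1.
#' @return An object of class `annotation_table`.
#' @export
annotation_table <- function(values, annotation_ids = colnames(values),
                             cell_ids = rownames(values),
                             encoding = c("numeric", "one-hot-categorical")) {
  encoding <- match.arg(encoding)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(values) == 0L) stop("annotation matrix is empty", call. = FALSE)
  if (any(!is.finite(values))) stop("annotation matrix has non-finite entries", call. = FALSE)
  if (is.null(annotation_ids)) annotation_ids <- paste0("ann_", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  annotation_ids <- .check_ids(annotation_ids, "annotation_ids")
  cell_ids <- .check_ids(cell_ids, "cell_ids")
  if (encoding == "one-hot-categorical" && any(abs(rowSums(values) - 1) > 1e-9))
    stop("one-hot annotation rows must sum to 1", call. = FALSE)
  dimnames(values) <- list(cell_ids, annotation_ids)
  structure(list(values = values, annotation_ids = annotation_ids,
                 cell_ids = cell_ids, encoding = encoding),
            class = "annotation_table")
}

#' One-hot encode categorical cell labels
#'
#' @param labels Character or factor vector of per-cell labels.
#' @param cell_ids Optional cell identifiers.
#' @return An `annotation_table` with encoding `"one-hot-categorical"`; one
#'   column per distinct label, in sorted label order.
#' @export
one_hot_labels <- function(labels, cell_ids = NULL) {
  labels <- as.character(labels)
  types <- sort(unique(labels))
  A <- matrix(0, length(labels), length(types),
              dimnames = list(cell_ids, types))
  A[cbind(seq_along(labels), match(labels, types))] <- 1
  annotation_table(A, annotation_ids = types, cell_ids = cell_ids,
                   encoding = "one-hot-categorical")
}

#' Validate a mapping problem
#'
#' Checks the joint invariants of the single-cell matrix, spatial matrix and
#' optional density prior: non-negative finite entries, unique ids, at least
#' one shared gene, and a simplex density of the right length.
#'
#' @param sc An `sc_matrix`.
#' @param sp A `spatial_matrix`.
#' @param d Optional `density_prior` (or numeric vector).
#' @return A list of class `validation_report` with elements `pass` (logical)
#'   and `violations` (character vector). Empty matrices or disjoint gene
#'   panels are hard errors, not report entries.
#' @export
validate_inputs <- function(sc, sp, d = NULL) {
  stopifnot(inherits(sc, "sc_matrix"), inherits(sp, "spatial_matrix"))
  shared <- intersect(sc$gene_ids, sp$gene_ids)
  if (length(shared) == 0L)
    stop("the two modalities share no genes; mapping requires a common panel",
         call. = FALSE)
  violations <- character(0)
  if (!is.null(d)) {
    dv <- as.numeric(d)
    if (length(dv) != nrow(sp$values))
      violations <- c(violations, sprintf(
        "density length %d != number of voxels %d", length(dv), nrow(sp$values)))
    if (any(dv < 0) || any(dv > 1))
      violations <- c(violations, "density entries outside [0, 1]")
    if (abs(sum(dv) - 1) > 1e-9)
      violations <- c(violations, sprintf("density sums to %.12g, not 1", sum(dv)))
  }
  if (!is.null(sc$labels) && length(sc$labels) != nrow(sc$values))
    violations <- c(violations, "labels length != number of cells")
  structure(list(pass = length(violations) == 0L, violations = violations,
                 n_shared_genes = length(shared)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(if (x$pass) "PASS" else "FAIL",
      sprintf(" (%d shared genes)\n", x$n_shared_genes))
  for (v in x$violations) cat(" - ", v, "\n", sep = "")
  invisible(x)
}

#' Restrict both modalities to a shared, ordered gene panel
#'
#' Intersects the gene sets of the two modalities (and optionally a training
#' panel) and reorders both matrices to the same gene order. When `panel` is
#' given its order is preserved; otherwise genes are sorted lexicographically.
#'
#' @param sc An `sc_matrix`.
#' @param sp A `spatial_matrix`.
#' @param panel Optional character vector of gene ids to further restrict to.
#' @return A list with elements `sc`, `sp` (gene-aligned) and `genes` (the
#'   shared ordered panel).
#' @export
intersect_genes <- function(sc, sp, panel = NULL) {
  stopifnot(inherits(sc, "sc_matrix"), inherits(sp, "spatial_matrix"))
  shared <- intersect(sc$gene_ids, sp$gene_ids)
  if (!is.null(panel)) {
    panel <- as.character(panel)
    shared <- panel[panel %in% shared]
  } else {
    shared <- sort(shared)
  }
  if (length(shared) == 0L)
    stop("no shared genes after intersection", call. = FALSE)
  list(
    sc = sc_matrix(sc$values[, shared, drop = FALSE], sc$cell_ids, shared,
                   labels = sc$labels),
    sp = spatial_matrix(sp$values[, shared, drop = FALSE], sp$voxel_ids,
                        shared, coords = sp$coords),
    genes = shared
  )
}

#' Library-size normalization
#'
#' Rescales every row (cell or voxel) so that its total equals `target_sum`,
#' removing library-size differences between observations. Rows with zero
#' total are rejected rather than silently kept.
#'
#' @param m An `sc_matrix` or `spatial_matrix`.
#' @param target_sum Per-row total after scaling; default 1e4.
#' @return The same container type with rescaled values.
#' @export
normalize_library_size <- function(m, target_sum = 1e4) {
  UseMethod("normalize_library_size")
}

.normalize_rows <- function(values, target_sum, ids) {
  totals <- rowSums(values)
  if (any(totals <= 0)) {
    bad <- ids[totals <= 0]
    stop("all-zero rows cannot be library-normalized: ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  values * (target_sum / totals)
}

#' @export
normalize_library_size.sc_matrix <- function(m, target_sum = 1e4) {
  m$values <- .normalize_rows(m$values, target_sum, m$cell_ids)
  m
}

#' @export
normalize_library_size.spatial_matrix <- function(m, target_sum = 1e4) {
  m$values <- .normalize_rows(m$values, target_sum, m$voxel_ids)
  m
}

#' Elementwise log(1 + x) transform
#'
#' @param m An `sc_matrix` or `spatial_matrix` with non-negative entries.
#' @return The same container type with `log1p`-transformed values.
#' @export
log1p_transform <- function(m) {
  stopifnot(inherits(m, "sc_matrix") || inherits(m, "spatial_matrix"))
  if (any(m$values < 0)) stop("log1p requires non-negative entries", call. = FALSE)
  m$values <- log1p(m$values)
  m
}

#' Per-gene spatial sparsity
#'
#' Sparsity of a gene is the fraction of voxels in which it is undetected
#' (measured value exactly zero), evaluated on raw counts.
#'
#' @param sp A `spatial_matrix`.
#' @return Named numeric vector in \[0, 1\], one entry per gene.
#' @export
compute_sparsity <- function(sp) {
  stopifnot(inherits(sp, "spatial_matrix"))
  colMeans(sp$values == 0)
}

#' @export
print.sc_matrix <- function(x, ...) {
  cat(sprintf("sc_matrix: %d cells x %d genes%s\n", nrow(x$values),
              ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(", %d labels", length(unique(x$labels)))))
  invisible(x)
}

#' @export
print.spatial_matrix <- function(x, ...) {
  cat(sprintf("spatial_matrix: %d voxels x %d genes%s\n", nrow(x$values),
              ncol(x$values),
              if (is.null(x$coords)) "" else " (with coordinates)"))
  invisible(x)
}
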