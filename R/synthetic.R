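# Ground-truth tissue simulator.
#
# Emulates the data regime the mapper is designed for: distinct cell-type
# expression signatures, spatially structured type occupancy (layered bands,
# as in cortical tissue), aggregation of cells into multi-cell capture spots,
# Poisson counting noise, Bernoulli dropout, and an arbitrary unit-of-measure
# mismatch between the single-cell and spatial modalities. Every quantity is
# derived from a recorded parameter set and seed, so a fixture regenerates
# bit-identically.

#' Cell-type expression signatures
#'
#' Per-type mean expression over genes: a shared positive baseline drawn per
#' gene, with a disjoint block of `markers_per_type` marker genes elevated
#' `effect`-fold in each type. With `effect = 1` all signatures collapse to
#' the baseline (degenerate control).
#'
#' @param n_types Number of cell types.
#' @param n_genes Number of genes (>= `n_types * markers_per_type`).
#' @param markers_per_type Marker genes per type (disjoint blocks).
#' @param effect Fold elevation of a type's markers over baseline.
#' @param seed RNG seed.
#' @return A types x genes matrix of non-negative means, with type and gene
#'   names.
#' @export
generate_profiles <- function(n_types, n_genes, markers_per_type, effect,
                              seed = 0L) {
  if (n_types * markers_per_type > n_genes)
    stop("need n_genes >= n_types * markers_per_type", call. = FALSE)
  .with_seed(seed, {
    baseline <- stats::runif(n_genes, 0.2, 1)
    sig <- matrix(rep(baseline, each = n_types), n_types, n_genes)
    for (t in seq_len(n_types)) {
      block <- ((t - 1L) * markers_per_type + 1L):(t * markers_per_type)
      sig[t, block] <- sig[t, block] * effect
    }
    dimnames(sig) <- list(paste0("type_", seq_len(n_types)),
                          sprintf("gene_%03d", seq_len(n_genes)))
    sig
  })
}

#' Spatial type occupancy and cell placement
#'
#' Builds a tissue of `n_voxels` voxels. `"layered"` layout splits the voxels
#' into contiguous bands, one dominant type per band (emulating cortical
#' layers); `"random"` gives every voxel the uniform occupancy. Cells are
#' then sampled per voxel: a Poisson(`cells_per_voxel`) count (at least 1)
#' with types drawn from the voxel's occupancy row.
#'
#' @param n_voxels Number of voxels (>= `n_types` for layered layout).
#' @param n_types Number of cell types.
#' @param layout `"layered"` or `"random"`.
#' @param cells_per_voxel Mean cells per voxel; default 3.
#' @param dominant_fraction Occupancy of the band's own type in layered
#'   layout; default 0.8, remainder spread over the other types.
#' @param seed RNG seed.
#' @return List with `type_occupancy` (voxels x types, rows sum to 1),
#'   `placement` (per-cell voxel index), `cell_types` (per-cell type index),
#'   `seg_counts` (cells per voxel).
#' @export
generate_tissue <- function(n_voxels, n_types, layout = c("layered", "random"),
                            cells_per_voxel = 3, dominant_fraction = 0.8,
                            seed = 0L) {
  layout <- match.arg(layout)
  if (layout == "layered" && n_voxels < n_types)
    stop("layered layout needs n_voxels >= n_types", call. = FALSE)
  occ <- matrix(1 / n_types, n_voxels, n_types)
  if (layout == "layered" && n_types > 1L) {
    band <- pmin(ceiling(seq_len(n_voxels) / (n_voxels / n_types)), n_types)
    off <- (1 - dominant_fraction) / (n_types - 1L)
    occ[] <- off
    occ[cbind(seq_len(n_voxels), band)] <- dominant_fraction
  }
  if (n_types == 1L) occ[] <- 1
  .with_seed(seed, {
    counts <- pmax(1L, stats::rpois(n_voxels, cells_per_voxel))
    placement <- rep(seq_len(n_voxels), counts)
    cell_types <- unlist(lapply(seq_len(n_voxels), function(j)
      sample.int(n_types, counts[j], replace = TRUE, prob = occ[j, ])))
    list(type_occupancy = occ, placement = placement,
         cell_types = cell_types, seg_counts = counts)
  })
}

#' Synthetic mapping problem with known ground truth
#'
#' Combines [generate_profiles()] and [generate_tissue()] into a full
#' fixture: typed cells placed in a structured tissue, with the single-cell
#' matrix holding each placed cell's expression (exact type signature, or a
#' Poisson draw from it when `sc_poisson_rate > 0`).
#'
#' @inheritParams generate_profiles
#' @inheritParams generate_tissue
#' @param sc_poisson_rate Gain of Poisson counting noise on the single-cell
#'   side: counts are drawn as `rpois(rate * mean) / rate`; 0 disables noise.
#' @param seed Master seed; profile, tissue and noise streams are derived
#'   from it.
#' @return A list of class `synthetic_truth`: `sc` (`sc_matrix` with
#'   labels), `signatures`, `placement`, `cell_types`, `type_occupancy`,
#'   `seg_counts`, `params`.
#' @export
synthetic_truth <- function(n_types = 5L, n_genes = 200L,
                            markers_per_type = 20L, effect = 8,
                            n_voxels = 100L, layout = "layered",
                            cells_per_voxel = 3, dominant_fraction = 0.8,
                            sc_poisson_rate = 0, seed = 0L) {
  params <- list(n_types = n_types, n_genes = n_genes,
                 markers_per_type = markers_per_type, effect = effect,
                 n_voxels = n_voxels, layout = layout,
                 cells_per_voxel = cells_per_voxel,
                 dominant_fraction = dominant_fraction,
                 sc_poisson_rate = sc_poisson_rate, seed = seed)
  sig <- generate_profiles(n_types, n_genes, markers_per_type, effect,
                           seed = seed)
  tissue <- generate_tissue(n_voxels, n_types, layout, cells_per_voxel,
                            dominant_fraction, seed = seed + 1L)
  n_cells <- length(tissue$placement)
  S <- sig[tissue$cell_types, , drop = FALSE]
  if (sc_poisson_rate > 0) {
    S <- .with_seed(seed + 2L, matrix(
      stats::rpois(length(S), sc_poisson_rate * S) / sc_poisson_rate,
      n_cells, ncol(S)))
  }
  sc <- sc_matrix(S, cell_ids = sprintf("cell_%04d", seq_len(n_cells)),
                  gene_ids = colnames(sig),
                  labels = rownames(sig)[tissue$cell_types])
  structure(list(sc = sc, signatures = sig, placement = tissue$placement,
                 cell_types = tissue$cell_types,
                 type_occupancy = tissue$type_occupancy,
                 seg_counts = tissue$seg_counts, params = params),
            class = "synthetic_truth")
}

#' Render the spatial measurement of a synthetic tissue
#'
#' `"spots"` resolution sums the profiles of the cells placed in each voxel
#' (multi-cell capture spots); `"single_cell"` renders one voxel per placed
#' cell, carrying that cell's own profile. Counting noise, dropout and a unit mismatch are then applied
#' in order: Poisson sampling at gain `poisson_rate` (0 = noiseless),
#' entrywise Bernoulli zeroing with probability `dropout_prob`, and
#' multiplication by `unit_scale`.
#'
#' @param truth A `synthetic_truth`.
#' @param resolution `"spots"` or `"single_cell"`.
#' @param poisson_rate Poisson gain; sampled counts are
#'   `rpois(rate * mean) / rate`; 0 disables sampling.
#' @param dropout_prob Probability that any entry is zeroed (technical
#'   dropout).
#' @param unit_scale Positive factor emulating a different unit of measure in
#'   the spatial modality.
#' @param seed RNG seed for the noise streams; defaults to the truth's seed
#'   plus 3.
#' @return A `spatial_matrix`. For `"single_cell"` the ground-truth mapping
#'   is cell `i` to voxel `i`.
#' @export
render_spatial <- function(truth, resolution = c("spots", "single_cell"),
                           poisson_rate = 0, dropout_prob = 0, unit_scale = 1,
                           seed = truth$params$seed + 3L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  resolution <- match.arg(resolution)
  profiles <- unname(truth$sc$values)   # the placed cells' own profiles
  if (resolution == "spots") {
    n_voxels <- truth$params$n_voxels
    G <- matrix(0, n_voxels, ncol(profiles))
    for (j in seq_len(n_voxels)) {
      here <- which(truth$placement == j)
      if (length(here))
        G[j, ] <- colSums(profiles[here, , drop = FALSE])
    }
    voxel_ids <- sprintf("voxel_%03d", seq_len(n_voxels))
  } else {
    G <- profiles
    voxel_ids <- paste0("sv_", truth$sc$cell_ids)
  }
  G <- .with_seed(seed, {
    if (poisson_rate > 0)
      G <- matrix(stats::rpois(length(G), poisson_rate * G) / poisson_rate,
                  nrow(G), ncol(G))
    if (dropout_prob > 0)
      G <- G * matrix(stats::rbinom(length(G), 1L, 1 - dropout_prob),
                      nrow(G), ncol(G))
    G * unit_scale
  })
  spatial_matrix(G, voxel_ids = voxel_ids, gene_ids = truth$sc$gene_ids)
}

#' The standard synthetic suite
#'
#' The default end-to-end fixture: 5 types, 200 genes (20 markers per type,
#' 8-fold effect), 100 voxels in layered bands, ~300 cells aggregated into
#' spots. Noiseless by default; dropout and Poisson noise are dials.
#'
#' @param seed Master seed; default 0.
#' @param dropout_prob,poisson_rate,unit_scale Spatial noise settings, see
#'   [render_spatial()].
#' @return List with `truth` (a `synthetic_truth`) and `sp` (the rendered
#'   spots `spatial_matrix`).
#' @export
standard_suite <- function(seed = 0L, dropout_prob = 0, poisson_rate = 0,
                           unit_scale = 1) {
  truth <- synthetic_truth(seed = seed)
  sp <- render_spatial(truth, "spots", poisson_rate = poisson_rate,
                       dropout_prob = dropout_prob, unit_scale = unit_scale)
  list(truth = truth, sp = sp)
}

#' Dominant ground-truth type per voxel
#'
#' @param truth A `synthetic_truth`.
#' @return Character vector: for every voxel, the most frequent placed type
#'   (lexicographically first on ties); NA for empty voxels.
#' @export
dominant_voxel_type <- function(truth) {
  types <- rownames(truth$signatures)
  vapply(seq_len(truth$params$n_voxels), function(j) {
    here <- truth$cell_types[truth$placement == j]
    if (!length(here)) return(NA_character_)
    tab <- table(factor(types[here], levels = types))
    names(tab)[which.max(tab)]
  }, character(1))
}

#' Cell-type recovery accuracy of a mapping
#'
#' Fits nothing: compares per-voxel called labels against the dominant
#' ground-truth type of each voxel, ignoring voxels with no truth or no call.
#'
#' @param truth A `synthetic_truth`.
#' @param called_labels Per-voxel labels, e.g. from
#'   [deterministic_celltype_map()].
#' @return Fraction of voxels called correctly.
#' @export
recovery_accuracy <- function(truth, called_labels) {
  ref <- dominant_voxel_type(truth)
  ok <- !is.na(ref) & !is.na(called_labels)
  if (!any(ok)) return(NA_real_)
  mean(called_labels[ok] == ref[ok])
}
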