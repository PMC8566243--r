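# Fixture builders shared across test files. All fixtures are generated in
# code under fixed seeds; nothing is read from disk.

# Self-mapping fixture: n cells with near-orthogonal block profiles, spatial
# side a permuted copy. The ground-truth assignment is voxel j <- cell
# perm[j].
self_mapping_fixture <- function(n, genes_per_cell = 2L, seed = 1L) {
  withr::local_seed(seed)
  ng <- n * genes_per_cell
  S <- matrix(runif(n * ng, 0.05, 0.25), n, ng)
  for (i in seq_len(n)) {
    block <- ((i - 1L) * genes_per_cell + 1L):(i * genes_per_cell)
    S[i, block] <- S[i, block] + 3 + runif(genes_per_cell)
  }
  perm <- sample(n)
  list(S = S, G = S[perm, , drop = FALSE], perm = perm,
       d = voxmap::uniform_density(n))
}

# Filtered-mode fixture: n_vox planted cells whose profiles match the voxels
# plus n_distract distractors expressing a disjoint gene block (all-zero in
# the spatial data).
planted_filter_fixture <- function(n_vox = 3L, n_distract = 3L) {
  A <- diag(n_vox) * 4 + 0.2
  B <- diag(n_distract) * 4 + 0.2
  S <- rbind(cbind(A, matrix(0.05, n_vox, n_distract)),
             cbind(matrix(0.05, n_distract, n_vox), B))
  G <- cbind(A, matrix(0, n_vox, n_distract))
  list(S = S, G = G, d = voxmap::uniform_density(n_vox),
       planted = seq_len(n_vox),
       distractors = n_vox + seq_len(n_distract))
}

# Small labelled single-cell fixture with planted marker genes:
# `markers_per_type` genes elevated by `effect` standard deviations in each
# type, remaining genes pure noise. Values are already on the standardized
# scale expected by rank_markers.
planted_marker_fixture <- function(n_types = 2L, cells_per_type = 10L,
                                   markers_per_type = 5L, n_noise = 10L,
                                   effect = 3, seed = 42L) {
  withr::local_seed(seed)
  n_cells <- n_types * cells_per_type
  ng <- n_types * markers_per_type + n_noise
  X <- matrix(rnorm(n_cells * ng), n_cells, ng)
  labels <- rep(paste0("T", seq_len(n_types)), each = cells_per_type)
  planted <- vector("list", n_types)
  for (t in seq_len(n_types)) {
    block <- ((t - 1L) * markers_per_type + 1L):(t * markers_per_type)
    X[labels == paste0("T", t), block] <-
      X[labels == paste0("T", t), block] + effect
    planted[[t]] <- sprintf("g%02d", block)
  }
  colnames(X) <- sprintf("g%02d", seq_len(ng))
  rownames(X) <- sprintf("c%02d", seq_len(n_cells))
  names(planted) <- paste0("T", seq_len(n_types))
  list(values = X, labels = labels, planted = planted)
}

# A mapping_result assembled by hand (no fitting), for isolating the
# transfer/scoring code from the optimizer.
manual_mapping_result <- function(M, f = NULL, cell_ids = NULL,
                                  voxel_ids = NULL) {
  structure(list(M = M, f = f, loss_trace = data.frame(epoch = 0, total = 0),
                 initial_total = 0, final_total = 0,
                 cell_ids = cell_ids, voxel_ids = voxel_ids,
                 config = list(mode = if (is.null(f)) "plain" else "filtered",
                               seed = 0L)),
            class = "mapping_result")
}

# Random simplex vector.
random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}
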