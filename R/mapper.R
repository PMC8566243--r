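# Gradient-based training of the cell-to-voxel mapping.
#
# Full-batch Adam on the unconstrained logits; the softmax/sigmoid
# parametrization keeps M row-stochastic and f in (0,1) at every step, so no
# projection is needed. All arithmetic is double precision and driven by a
# single seeded RNG so that a fit is bit-reproducible from its settings.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls do not perturb user sessions.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default epoch count for a mapping use case
#'
#' Fixed epoch budgets by data regime: 1200 for targeted single-cell
#' resolution data, 300 for probabilistic mapping onto multi-cell spots, 6000
#' for spot deconvolution with a learned filter, 150 for coarse atlas-style
#' grids. Always overridable via the `epochs` argument of [fit_mapping()].
#'
#' @param use_case One of `"targeted"`, `"spots"`, `"deconvolution"`,
#'   `"atlas"`.
#' @return Integer epoch count.
#' @export
default_epochs <- function(use_case = c("targeted", "spots", "deconvolution",
                                        "atlas")) {
  switch(match.arg(use_case),
         targeted = 1200L, spots = 300L, deconvolution = 6000L, atlas = 150L)
}

#' Fit a probabilistic cell-to-voxel mapping
#'
#' Minimizes the composite mapping objective with full-batch Adam. In
#' `"plain"` mode every cell is mapped; in `"filtered"` mode a per-cell
#' filter is learned jointly with the mapping so that approximately
#' `n_target_cells` cells are retained.
#'
#' @param S Cells x genes matrix (or `sc_matrix`) on the training panel.
#' @param G Voxels x genes matrix (or `spatial_matrix`), same gene order.
#' @param d Density prior over voxels.
#' @param mode `"plain"` or `"filtered"`.
#' @param n_target_cells Target number of mapped cells (filtered mode; must
#'   not exceed the number of cells).
#' @param epochs Number of full-batch gradient steps; default 1000.
#' @param lr Adam learning rate; default 0.1.
#' @param seed Integer seed for the Gaussian logit initialization.
#' @param weights Density / gene-axis / voxel-axis term weights, default
#'   `c(1, 1, 1)`.
#' @param lambda_r1 Entropy-regularizer weight, default 0.
#' @param trace_every Record the loss breakdown every this many epochs (the
#'   initial and final epochs are always recorded); default 10.
#' @param verbose Print loss every 100 epochs.
#' @return A list of class `mapping_result`: `M` (row-stochastic cells x
#'   voxels), `f` (filter values or NULL), `loss_trace` (data.frame of
#'   recorded breakdowns), `config` (all settings including the seed),
#'   and the id vectors when the inputs carried them.
#' @export
fit_mapping <- function(S, G, d, mode = c("plain", "filtered"),
                        n_target_cells = NULL, epochs = 1000L, lr = 0.1,
                        seed = 0L, weights = c(1, 1, 1), lambda_r1 = 0,
                        trace_every = 10L, verbose = FALSE) {
  mode <- match.arg(mode)
  cell_ids <- voxel_ids <- NULL
  if (inherits(S, "sc_matrix")) { cell_ids <- S$cell_ids; S <- S$values }
  if (inherits(G, "spatial_matrix")) { voxel_ids <- G$voxel_ids; G <- G$values }
  S <- as.matrix(S); G <- as.matrix(G)
  d <- as.numeric(d)
  n_cells <- nrow(S); n_voxels <- nrow(G)
  if (mode == "filtered") {
    if (is.null(n_target_cells))
      stop("filtered mode requires n_target_cells", call. = FALSE)
    if (n_target_cells > n_cells)
      stop("n_target_cells (", n_target_cells, ") exceeds available cells (",
           n_cells, ")", call. = FALSE)
  }
  epochs <- as.integer(epochs)

  init <- .with_seed(seed, {
    list(M = matrix(stats::rnorm(n_cells * n_voxels), n_cells, n_voxels),
         f = if (mode == "filtered") stats::rnorm(n_cells) else NULL)
  })
  Mz <- init$M; fz <- init$f

  # Adam state
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  mM <- vM <- matrix(0, n_cells, n_voxels)
  if (mode == "filtered") mf <- vf <- numeric(n_cells)

  trace <- list()
  record <- function(epoch, bd) {
    trace[[length(trace) + 1L]] <<- data.frame(
      epoch = epoch, density_term = bd$density_term,
      gene_axis_term = bd$gene_axis_term, voxel_axis_term = bd$voxel_axis_term,
      entropy_term = bd$entropy_term, count_term = bd$count_term,
      filter_reg_term = bd$filter_reg_term, total = bd$total)
  }

  ev <- .loss_and_grad(Mz, fz, S, G, d, mode, n_target_cells, weights,
                       lambda_r1, want_grad = TRUE)
  record(0L, ev$breakdown)
  initial_total <- ev$breakdown$total

  if (epochs > 0L) {
    for (t in seq_len(epochs)) {
      if (!is.finite(ev$breakdown$total)) {
        terms <- unlist(ev$breakdown[c("density_term", "gene_axis_term",
                                       "voxel_axis_term", "entropy_term",
                                       "count_term", "filter_reg_term")])
        stop("non-finite loss at epoch ", t - 1L, "; offending term(s): ",
             paste(names(terms)[!is.finite(terms)], collapse = ", "),
             call. = FALSE)
      }
      mM <- b1 * mM + (1 - b1) * ev$grad_M_logits
      vM <- b2 * vM + (1 - b2) * ev$grad_M_logits^2
      Mz <- Mz - lr * (mM / (1 - b1^t)) / (sqrt(vM / (1 - b2^t)) + adam_eps)
      if (mode == "filtered") {
        mf <- b1 * mf + (1 - b1) * ev$grad_f_logits
        vf <- b2 * vf + (1 - b2) * ev$grad_f_logits^2
        fz <- fz - lr * (mf / (1 - b1^t)) / (sqrt(vf / (1 - b2^t)) + adam_eps)
      }
      ev <- .loss_and_grad(Mz, fz, S, G, d, mode, n_target_cells, weights,
                           lambda_r1, want_grad = t < epochs)
      if (t %% trace_every == 0L || t == epochs) record(t, ev$breakdown)
      if (verbose && t %% 100L == 0L)
        message(sprintf("epoch %d: loss %.6g", t, ev$breakdown$total))
    }
  }

  M <- softmax_rows(Mz)
  f <- if (mode == "filtered") sigmoid_filter(fz) else NULL
  if (!is.null(cell_ids)) rownames(M) <- cell_ids
  if (!is.null(voxel_ids)) colnames(M) <- voxel_ids
  if (!is.null(f) && !is.null(cell_ids)) names(f) <- cell_ids

  structure(list(
    M = M, f = f,
    loss_trace = do.call(rbind, trace),
    initial_total = initial_total, final_total = ev$breakdown$total,
    cell_ids = cell_ids, voxel_ids = voxel_ids,
    config = list(mode = mode, n_target_cells = n_target_cells,
                  epochs = epochs, lr = lr, seed = seed,
                  weights = as.numeric(weights), lambda_r1 = lambda_r1)),
    class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("mapping_result: %d cells x %d voxels (%s mode, %d epochs, seed %d)\n",
              nrow(x$M), ncol(x$M), x$config$mode, x$config$epochs,
              x$config$seed))
  cat(sprintf("  loss: %.6g -> %.6g\n", x$initial_total, x$final_total))
  if (!is.null(x$f))
    cat(sprintf("  filter: %d of %d cells retained (f > 0.5)\n",
                sum(x$f > 0.5), length(x$f)))
  invisible(x)
}

#' Fraction of cells with a peaked spatial distribution
#'
#' Convergence diagnostic: the fraction of (filter-retained) cells whose
#' highest single-voxel probability exceeds `threshold`. After convergence on
#' single-cell-resolution data nearly all mapped cells should be assigned to
#' one voxel with probability above 0.5.
#'
#' @param result A `mapping_result`.
#' @param threshold Probability threshold, default 0.5.
#' @return Scalar in \[0, 1\].
#' @export
mapping_sharpness <- function(result, threshold = 0.5) {
  keep <- if (is.null(result$f)) rep(TRUE, nrow(result$M)) else result$f > 0.5
  if (!any(keep)) return(NA_real_)
  mean(apply(result$M[keep, , drop = FALSE], 1L, max) > threshold)
}

#' Fit configuration for targeted (single-cell-resolution) spatial data
#'
#' For targeted in situ technologies each voxel is one segmented cell, so the
#' density prior is uniform. When the dissociated cells outnumber the voxels
#' the mapping is filtered with `n_target_cells = n_voxels`, enforcing a
#' one-to-one correspondence; otherwise every cell is mapped in plain mode.
#'
#' @param S Cells x genes matrix or `sc_matrix`.
#' @param G Voxels x genes matrix or `spatial_matrix`.
#' @return List with `mode`, `n_target_cells` (NULL in plain mode) and `d`
#'   (uniform `density_prior`), suitable for splicing into [fit_mapping()].
#' @export
mode_targeted <- function(S, G) {
  n_cells <- if (inherits(S, "sc_matrix")) nrow(S$values) else nrow(S)
  n_voxels <- if (inherits(G, "spatial_matrix")) nrow(G$values) else nrow(G)
  if (n_cells >= n_voxels) {
    list(mode = "filtered", n_target_cells = n_voxels, d = uniform_density(n_voxels))
  } else {
    list(mode = "plain", n_target_cells = NULL, d = uniform_density(n_voxels))
  }
}

#' Fit configuration for spot deconvolution
#'
#' For multi-cell capture spots with a nuclear segmentation of the underlying
#' histology: the density prior is proportional to the per-spot segmented-cell
#' counts and the filtered objective retains `n_target_cells = sum(counts)`
#' cells in total.
#'
#' @param S Cells x genes matrix or `sc_matrix`.
#' @param G Voxels x genes matrix or `spatial_matrix`.
#' @param seg_counts Per-voxel segmented cell counts.
#' @return List with `mode = "filtered"`, `n_target_cells` and `d`.
#' @export
mode_deconvolution <- function(S, G, seg_counts) {
  n_cells <- if (inherits(S, "sc_matrix")) nrow(S$values) else nrow(S)
  n_voxels <- if (inherits(G, "spatial_matrix")) nrow(G$values) else nrow(G)
  seg_counts <- as.numeric(seg_counts)
  if (length(seg_counts) != n_voxels)
    stop("seg_counts length must equal number of voxels", call. = FALSE)
  n_seg <- sum(seg_counts)
  if (n_seg <= 0) stop("segmented counts are all zero", call. = FALSE)
  if (n_seg > n_cells)
    stop("total segmented cells (", n_seg, ") exceed available profiles (",
         n_cells, ")", call. = FALSE)
  list(mode = "filtered", n_target_cells = n_seg,
       d = density_from_segmentation(seg_counts))
}
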