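# Loss terms of the mapping objective and their analytic gradients.
#
# The mapping matrix M (cells x voxels, row-stochastic) is parametrized as the
# row-wise softmax of an unconstrained logit matrix; the optional per-cell
# filter f is the sigmoid of an unconstrained logit vector. The objective
# combines:
#   density term    KL(m || d), m = predicted per-voxel density
#   gene-axis term  sum_k cos_sim((M'S)[,k], G[,k])   (subtracted)
#   voxel-axis term sum_j cos_sim((M'S)[j,], G[j,])   (subtracted)
#   entropy term    -sum_ij M_ij log M_ij, weighted by lambda_r1
#   count term      |sum_i f_i - n_target_cells|       (filtered mode)
#   filter reg      sum_i (f_i - f_i^2)                (filtered mode)
# In filtered mode the single-cell matrix entering the cosine terms is
# diag(f) S and the density is computed over filter-weighted cells.
#
# Gradients are derived analytically (chain rule through softmax/sigmoid) and
# verified against central finite differences in the test suite.

.EPS <- 1e-8

#' Row-wise softmax
#'
#' Maps an unconstrained cells x voxels logit matrix to a row-stochastic
#' matrix, numerically stabilized by row-max subtraction so that arbitrarily
#' large logits do not overflow.
#'
#' @param logits Numeric matrix with finite entries.
#' @return Matrix of the same shape; every row is non-negative and sums to 1.
#' @export
softmax_rows <- function(logits) {
  logits <- as.matrix(logits)
  if (any(!is.finite(logits))) stop("non-finite logits", call. = FALSE)
  shifted <- exp(logits - apply(logits, 1L, max))
  shifted / rowSums(shifted)
}

#' Elementwise sigmoid
#'
#' Maps unconstrained per-cell filter logits into (0, 1).
#'
#' @param x Numeric vector with finite entries.
#' @return `1 / (1 + exp(-x))`.
#' @export
sigmoid_filter <- function(x) {
  if (any(!is.finite(x))) stop("non-finite filter logits", call. = FALSE)
  1 / (1 + exp(-x))
}

#' Predicted per-voxel cell density
#'
#' Unfiltered: `m_j = sum_i M_ij / n_cells`. Filtered:
#' `m_j = sum_i f_i M_ij / sum_i f_i`, the density of filter-retained cells.
#' Both are probability simplex vectors because M is row-stochastic.
#'
#' @param M Row-stochastic cells x voxels matrix.
#' @param f Optional per-cell filter values in \[0, 1\].
#' @return Numeric per-voxel vector summing to 1.
#' @export
predicted_density <- function(M, f = NULL) {
  if (is.null(f)) return(colSums(M) / nrow(M))
  F_tot <- sum(f)
  if (F_tot <= 0) stop("filter sums to zero; no cells retained", call. = FALSE)
  colSums(f * M) / F_tot
}

#' Kullback-Leibler divergence between two simplex vectors
#'
#' `KL(m || d) = sum_j m_j log(m_j / d_j)`, with both arguments clamped below
#' at 1e-8 inside the logarithm. Non-negative, and zero iff the two
#' distributions coincide.
#'
#' @param m,d Probability vectors of equal length.
#' @return Scalar divergence (nats).
#' @export
kl_divergence <- function(m, d) {
  m <- as.numeric(m); d <- as.numeric(d)
  if (length(m) != length(d)) stop("length mismatch in KL divergence", call. = FALSE)
  mc <- pmax(m, .EPS); dc <- pmax(d, .EPS)
  sum(mc * log(mc / dc))
}

# Cosine similarity between matched columns of two matrices, plus the gradient
# of sum(similarities) with respect to the first matrix. An all-zero vector on
# either side contributes similarity 0 with zero gradient.
.cosine_cols <- function(P, G) {
  pn <- sqrt(colSums(P^2))
  gn <- sqrt(colSums(G^2))
  live <- pn > 0 & gn > 0
  num <- colSums(P * G)
  cs <- numeric(ncol(P))
  cs[live] <- num[live] / (pmax(pn[live] * gn[live], .EPS))
  grad <- matrix(0, nrow(P), ncol(P))
  if (any(live)) {
    denom <- pmax(pn * gn, .EPS)
    gcol <- sweep(G, 2L, denom, "/") -
      sweep(P, 2L, cs / pmax(pn^2, .EPS), "*")
    grad[, live] <- gcol[, live, drop = FALSE]
  }
  list(value = sum(cs), per_item = cs, grad = grad)
}

#' Gene-axis and voxel-axis cosine similarity terms
#'
#' With predicted spatial expression `P = t(M) %*% S` (or
#' `t(M) %*% (f * S)` under a filter), the gene-axis term sums, over genes,
#' the cosine similarity between the predicted and measured per-voxel profile
#' of each gene; the voxel-axis term sums, over voxels, the similarity between
#' predicted and measured per-gene profiles. Cosine similarity is scale
#' invariant, so the two modalities need not share a unit of measure.
#'
#' @param M Row-stochastic cells x voxels matrix.
#' @param S Cells x genes single-cell expression (training panel, same gene
#'   order as `G`).
#' @param G Voxels x genes spatial expression.
#' @param f Optional per-cell filter values.
#' @return List with `gene_axis_term` and `voxel_axis_term` (each a sum of
#'   cosine similarities, at most the number of genes resp. voxels).
#' @export
cosine_terms <- function(M, S, G, f = NULL) {
  if (ncol(S) != ncol(G)) stop("S and G must share the same gene panel", call. = FALSE)
  if (nrow(M) != nrow(S) || ncol(M) != nrow(G))
    stop("shape mismatch between M, S and G", call. = FALSE)
  Sf <- if (is.null(f)) S else f * S
  P <- crossprod(M, Sf)                       # voxels x genes
  list(gene_axis_term = .cosine_cols(P, G)$value,
       voxel_axis_term = .cosine_cols(t(P), t(G))$value)
}

#' Entropy of the per-cell spatial distributions
#'
#' `-sum_ij M_ij log M_ij` (clamped logs): zero for one-hot rows, maximal for
#' uniform rows. Added to the loss with weight `lambda_r1`, so minimizing the
#' loss sharpens each cell's spatial distribution.
#'
#' @param M Row-stochastic cells x voxels matrix.
#' @return Scalar entropy (nats), `>= 0`.
#' @export
entropy_regularizer <- function(M) {
  -sum(M * log(pmax(M, .EPS)))
}

#' Count and filter-regularizer terms
#'
#' The count term `|sum_i f_i - n_target_cells|` softly constrains the number
#' of retained cells; the filter regularizer `sum_i (f_i - f_i^2)` promotes
#' Boolean filter values.
#'
#' @param f Per-cell filter values in \[0, 1\].
#' @param n_target_cells Target number of mapped cells.
#' @return List with `count_term` and `filter_reg_term`.
#' @export
count_and_filter_terms <- function(f, n_target_cells) {
  list(count_term = abs(sum(f) - n_target_cells),
       filter_reg_term = sum(f - f^2))
}

#' Mapping loss
#'
#' Evaluates the full objective from unconstrained logits. In `"plain"` mode
#' the loss is
#' `w_d * KL(m, d) - w_g * gene_axis - w_v * voxel_axis + lambda_r1 * entropy`;
#' in `"filtered"` mode the density and cosine terms use the filter-weighted
#' cells and the count and filter-regularizer terms are added.
#'
#' @param M_logits Cells x voxels unconstrained matrix.
#' @param f_logits Per-cell unconstrained filter logits (`"filtered"` mode).
#' @param S Cells x genes expression on the training panel.
#' @param G Voxels x genes spatial expression, same gene order.
#' @param d Density prior (simplex vector over voxels).
#' @param mode `"plain"` or `"filtered"`.
#' @param n_target_cells Target mapped-cell count (required in filtered mode).
#' @param weights Length-3 numeric: density, gene-axis and voxel-axis weights
#'   (`w_d`, `w_g`, `w_v`); all default to 1 as in the printed objective.
#' @param lambda_r1 Entropy-regularizer weight; default 0 (off).
#' @return A list of class `loss_breakdown`: each term on its natural scale
#'   (before weighting) plus `total`, the weighted sum actually minimized.
#' @export
mapping_loss <- function(M_logits, f_logits = NULL, S, G, d,
                         mode = c("plain", "filtered"), n_target_cells = NULL,
                         weights = c(1, 1, 1), lambda_r1 = 0) {
  mode <- match.arg(mode)
  .loss_and_grad(M_logits, f_logits, S, G, d, mode, n_target_cells,
                 weights, lambda_r1, want_grad = FALSE)$breakdown
}

# Core evaluation: loss breakdown and (optionally) analytic gradients with
# respect to the logits. Single code path keeps value and gradient consistent.
.loss_and_grad <- function(M_logits, f_logits, S, G, d, mode, n_target_cells,
                           weights, lambda_r1, want_grad = TRUE) {
  stopifnot(length(weights) == 3L)
  d <- as.numeric(d)
  n_cells <- nrow(M_logits); n_voxels <- ncol(M_logits)
  if (nrow(S) != n_cells) stop("S rows must match cells", call. = FALSE)
  if (nrow(G) != n_voxels) stop("G rows must match voxels", call. = FALSE)
  if (ncol(S) != ncol(G)) stop("S and G gene panels differ", call. = FALSE)
  if (length(d) != n_voxels) stop("density length must match voxels", call. = FALSE)
  filtered <- mode == "filtered"
  if (filtered && is.null(n_target_cells))
    stop("filtered mode requires n_target_cells", call. = FALSE)
  w_d <- weights[1]; w_g <- weights[2]; w_v <- weights[3]

  M <- softmax_rows(M_logits)
  f <- if (filtered) sigmoid_filter(f_logits) else NULL

  Sf <- if (filtered) f * S else S
  P <- crossprod(M, Sf)                                  # voxels x genes

  # density term
  F_tot <- if (filtered) sum(f) else n_cells
  m_hat <- if (filtered) colSums(f * M) / F_tot else colSums(M) / n_cells
  density_term <- kl_divergence(m_hat, d)

  # cosine terms along both axes
  gene_cos <- .cosine_cols(P, G)
  vox_cos <- .cosine_cols(t(P), t(G))

  entropy_term <- entropy_regularizer(M)

  count_term <- 0; filter_reg_term <- 0
  if (filtered) {
    cf <- count_and_filter_terms(f, n_target_cells)
    count_term <- cf$count_term
    filter_reg_term <- cf$filter_reg_term
  }

  total <- w_d * density_term - w_g * gene_cos$value - w_v * vox_cos$value +
    lambda_r1 * entropy_term + count_term + filter_reg_term

  breakdown <- structure(list(
    density_term = density_term,
    gene_axis_term = gene_cos$value,
    voxel_axis_term = vox_cos$value,
    entropy_term = entropy_term,
    count_term = count_term,
    filter_reg_term = filter_reg_term,
    total = total,
    weights = c(w_d = w_d, w_g = w_g, w_v = w_v), lambda_r1 = lambda_r1,
    mode = mode), class = "loss_breakdown")
  if (!want_grad) return(list(breakdown = breakdown))

  # --- gradients ---
  # dL/dP from both cosine terms (the voxel-axis gradient comes back
  # transposed because it was computed on t(P)).
  dL_dP <- -w_g * gene_cos$grad - w_v * t(vox_cos$grad)

  # P = t(M) %*% (f*S): dL/dM += (f*S) %*% t(dL_dP); dL/df via M and S.
  dL_dM <- Sf %*% t(dL_dP)                               # cells x voxels

  # density term: dKL/dm_j = log(m_j/d_j) + 1 on the clamped region
  g_dens <- ifelse(m_hat > .EPS, log(pmax(m_hat, .EPS) / pmax(d, .EPS)) + 1, 0)
  if (filtered) {
    dL_dM <- dL_dM + w_d * outer(f, g_dens) / F_tot
  } else {
    dL_dM <- dL_dM + w_d * matrix(g_dens, n_cells, n_voxels, byrow = TRUE) / n_cells
  }

  if (lambda_r1 != 0) {
    dL_dM <- dL_dM - lambda_r1 * (log(pmax(M, .EPS)) + 1) * (M > .EPS)
  }

  # chain through row softmax: dL/dZ = M * (dL/dM - rowSums(dL/dM * M))
  grad_M_logits <- M * (dL_dM - rowSums(dL_dM * M))

  grad_f_logits <- NULL
  if (filtered) {
    # cosine terms: dP_jk/df_i = M_ij S_ik
    dL_df <- rowSums((S %*% t(dL_dP)) * M)
    # density: dm_j/df_i = (M_ij - m_j) / F_tot
    dL_df <- dL_df + w_d * (as.numeric(M %*% g_dens) - sum(g_dens * m_hat)) / F_tot
    # count term subgradient and filter regularizer
    dL_df <- dL_df + sign(sum(f) - n_target_cells) + (1 - 2 * f)
    grad_f_logits <- dL_df * f * (1 - f)
  }

  list(breakdown = breakdown, grad_M_logits = grad_M_logits,
       grad_f_logits = grad_f_logits)
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss (%s): total %.6g | KL %.4g  gene-cos %.4g  voxel-cos %.4g  H %.4g  count %.4g  freg %.4g\n",
    x$mode, x$total, x$density_term, x$gene_axis_term, x$voxel_axis_term,
    x$entropy_term, x$count_term, x$filter_reg_term))
  invisible(x)
}
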