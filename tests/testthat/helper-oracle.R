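# Independent oracles: naive arithmetic implementations of the objective and
# exhaustive searches over hard assignments. These deliberately avoid the
# package's own loss/gradient code paths.

oracle_cos <- function(u, v, eps = 1e-8) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / max(nu * nv, eps)
}

# Full objective by direct summation. M row-stochastic, f in [0,1] or NULL.
oracle_loss <- function(M, f, S, G, d, n_target = NULL,
                        weights = c(1, 1, 1), lambda = 0, eps = 1e-8) {
  filtered <- !is.null(f)
  Sf <- if (filtered) diag(f, nrow = length(f)) %*% S else S
  P <- t(M) %*% Sf
  m <- if (filtered) as.numeric(t(M) %*% f) / sum(f) else colSums(M) / nrow(M)
  kl <- sum(pmax(m, eps) * log(pmax(m, eps) / pmax(d, eps)))
  gene <- sum(vapply(seq_len(ncol(P)), function(k) oracle_cos(P[, k], G[, k]),
                     numeric(1)))
  vox <- sum(vapply(seq_len(nrow(P)), function(j) oracle_cos(P[j, ], G[j, ]),
                    numeric(1)))
  H <- -sum(M * log(pmax(M, eps)))
  cnt <- if (filtered) abs(sum(f) - n_target) else 0
  freg <- if (filtered) sum(f - f^2) else 0
  weights[1] * kl - weights[2] * gene - weights[3] * vox + lambda * H +
    cnt + freg
}

# All permutations of 1..n as rows of a matrix.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- all_perms(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
  dimnames(out) <- NULL
  out
}

# Exhaustive minimizer of the plain objective over hard one-to-one
# assignments (M a permutation matrix), for self-mapping fixtures with
# uniform density. Returns the best permutation (voxel j <- cell perm[j]).
brute_force_permutation <- function(S, G, d, weights = c(1, 1, 1)) {
  n <- nrow(S)
  stopifnot(nrow(G) == n)
  perms <- all_perms(n)
  Gcn <- sqrt(colSums(G^2))
  Grn <- sqrt(rowSums(G^2))
  kl_const <- sum((1 / n) * log((1 / n) / pmax(d, 1e-8)))  # m uniform for any permutation
  best <- NULL; best_loss <- Inf
  for (r in seq_len(nrow(perms))) {
    p <- as.integer(perms[r, ])
    Sp <- S[p, , drop = FALSE]          # rows of t(M) %*% S for permutation M
    gene <- sum(ifelse(Gcn > 0, colSums(Sp * G) /
                         pmax(sqrt(colSums(Sp^2)) * Gcn, 1e-8), 0))
    vox <- sum(ifelse(Grn > 0, rowSums(Sp * G) /
                        pmax(sqrt(rowSums(Sp^2)) * Grn, 1e-8), 0))
    loss <- weights[1] * kl_const - weights[2] * gene - weights[3] * vox
    if (loss < best_loss) { best_loss <- loss; best <- p }
  }
  list(perm = best, loss = best_loss)
}

# Exhaustive minimizer of the filtered objective over hard subset choices
# (|subset| = n_target, f boolean) and hard one-to-one assignments of the
# subset to voxels. Returns the best subset (sorted cell indices).
brute_force_subset <- function(S, G, d, n_target, weights = c(1, 1, 1)) {
  n_cells <- nrow(S); n_vox <- nrow(G)
  stopifnot(n_target == n_vox)
  subsets <- utils::combn(n_cells, n_target)
  perms <- all_perms(n_target)
  best <- NULL; best_loss <- Inf
  for (s in seq_len(ncol(subsets))) {
    sub <- subsets[, s]
    f <- as.numeric(seq_len(n_cells) %in% sub)
    for (r in seq_len(nrow(perms))) {
      M <- matrix(1 / n_vox, n_cells, n_vox)   # unselected rows: irrelevant
      M[sub, ] <- 0
      M[cbind(sub[perms[r, ]], seq_len(n_vox))] <- 1
      loss <- oracle_loss(M, f, S, G, d, n_target = n_target,
                          weights = weights)
      if (loss < best_loss) { best_loss <- loss; best <- sort(sub) }
    }
  }
  list(subset = best, loss = best_loss)
}

# Central finite-difference gradient of the total loss wrt the logits.
numeric_gradients <- function(M_logits, f_logits, S, G, d, mode,
                              n_target = NULL, weights = c(1, 1, 1),
                              lambda = 0, h = 1e-6) {
  # value path built from the naive oracle, not the package's loss code
  f_of <- function(Mz, fz) {
    M <- exp(Mz - apply(Mz, 1L, max)); M <- M / rowSums(M)
    f <- if (is.null(fz)) NULL else 1 / (1 + exp(-fz))
    oracle_loss(M, f, S, G, d,
                n_target = if (mode == "filtered") n_target else NULL,
                weights = weights, lambda = lambda)
  }
  gM <- matrix(0, nrow(M_logits), ncol(M_logits))
  for (idx in seq_along(M_logits)) {
    Mp <- M_logits; Mp[idx] <- Mp[idx] + h
    Mm <- M_logits; Mm[idx] <- Mm[idx] - h
    gM[idx] <- (f_of(Mp, f_logits) - f_of(Mm, f_logits)) / (2 * h)
  }
  gf <- NULL
  if (!is.null(f_logits)) {
    gf <- numeric(length(f_logits))
    for (i in seq_along(f_logits)) {
      fp <- f_logits; fp[i] <- fp[i] + h
      fm <- f_logits; fm[i] <- fm[i] - h
      gf[i] <- (f_of(M_logits, fp) - f_of(M_logits, fm)) / (2 * h)
    }
  }
  list(M = gM, f = gf)
}
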