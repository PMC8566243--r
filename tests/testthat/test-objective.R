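test_that("softmax rows are stable probability vectors", {
  expect_equal(unname(softmax_rows(matrix(c(0, 0), 1, 2))[1, ]), c(0.5, 0.5))
  expect_equal(unname(softmax_rows(matrix(c(log(3), 0), 1, 2))[1, ]),
               c(0.75, 0.25))
  big <- softmax_rows(matrix(c(1000, 0), 1, 2))
  expect_true(all(is.finite(big)))
  expect_equal(unname(big[1, ]), c(1, 0), tolerance = 1e-12)

  # property: rows sum to 1 for random logits
  withr::local_seed(2)
  for (i in 1:1000) {
    M <- softmax_rows(matrix(rnorm(12, sd = 5), 3, 4))
    expect_lt(max(abs(rowSums(M) - 1)), 1e-6)
  }
})

test_that("sigmoid filter is symmetric and bounded", {
  expect_equal(sigmoid_filter(0), 0.5)
  expect_gt(sigmoid_filter(50), 1 - 1e-12)
  x <- c(-2.5, 0.3, 4)
  expect_equal(sigmoid_filter(-x), 1 - sigmoid_filter(x))
})

test_that("predicted density is a simplex, filtered and not", {
  M <- rbind(c(1, 0), c(0, 1))
  expect_equal(predicted_density(M), c(0.5, 0.5))
  expect_equal(predicted_density(M, f = c(1, 0)), c(1, 0))
  expect_error(predicted_density(M, f = c(0, 0)), "zero")

  withr::local_seed(3)
  for (i in 1:50) {
    M <- softmax_rows(matrix(rnorm(20), 4, 5))
    expect_equal(sum(predicted_density(M)), 1, tolerance = 1e-12)
    f <- runif(4)
    expect_equal(sum(predicted_density(M, f)), 1, tolerance = 1e-12)
  }
})

test_that("KL divergence matches independent arithmetic and Gibbs' inequality", {
  d <- c(0.3, 0.7)
  expect_equal(kl_divergence(d, d), 0)
  # 0.5 ln 2 + 0.5 ln(2/3), evaluated independently
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_error(kl_divergence(c(1), c(0.5, 0.5)), "length")

  withr::local_seed(4)
  for (i in 1:1000) {
    n <- sample(2:10, 1)
    expect_gte(kl_divergence(random_simplex(n), random_simplex(n)), 0)
  }
})

test_that("cosine terms hit their closed forms and are scale invariant", {
  withr::local_seed(6)
  S <- matrix(runif(12, 0.1, 2), 3, 4)
  M <- diag(3)
  G <- S                                   # P = t(I) S = S: perfect prediction
  ct <- cosine_terms(M, S, G)
  expect_equal(ct$gene_axis_term, 4, tolerance = 1e-9)
  expect_equal(ct$voxel_axis_term, 3, tolerance = 1e-9)
  ct_scaled <- cosine_terms(M, S, G * 13)
  expect_equal(ct_scaled$gene_axis_term, 4, tolerance = 1e-9)
  expect_equal(cosine_terms(M, S * 0.01, G)$voxel_axis_term, 3,
               tolerance = 1e-9)

  # single gene: P = [1,1], G = [1,0] -> cos = 1/sqrt(2)
  one <- cosine_terms(diag(2), matrix(1, 2, 1), matrix(c(1, 0), 2, 1))
  expect_equal(one$gene_axis_term, 1 / sqrt(2), tolerance = 1e-12)

  expect_error(cosine_terms(diag(2), matrix(1, 2, 2), matrix(1, 2, 3)),
               "gene panel")
})

test_that("entropy regularizer is zero at one-hot and log(n) at uniform", {
  expect_equal(entropy_regularizer(rbind(c(1, 0), c(0, 1))), 0,
               tolerance = 1e-6)
  expect_equal(entropy_regularizer(matrix(1 / 5, 1, 5)), log(5),
               tolerance = 1e-9)
  # sharpening a row decreases entropy monotonically
  hs <- sapply(c(0, 1, 2, 4, 8), function(a)
    entropy_regularizer(softmax_rows(matrix(c(a, 0, 0), 1, 3))))
  expect_true(all(diff(hs) < 0))
})

test_that("count and filter-regularizer terms match their definitions", {
  f <- c(1, 1, 0, 0)
  out <- count_and_filter_terms(f, 2)
  expect_equal(out$count_term, 0)
  expect_equal(out$filter_reg_term, 0)
  out2 <- count_and_filter_terms(rep(0.5, 4), 2)
  expect_equal(out2$count_term, 0)
  expect_equal(out2$filter_reg_term, 1)
  out3 <- count_and_filter_terms(rep(0, 4), 3)
  expect_equal(out3$count_term, 3)
  expect_equal(out3$filter_reg_term, 0)
})

test_that("loss on the identity fixture composes the terms correctly", {
  withr::local_seed(8)
  S <- rbind(c(5, 0.1, 0.1, 0.1), c(0.1, 5, 0.1, 0.1))   # 2 distinct cells
  G <- S
  d <- uniform_density(2)
  # M = identity permutation via large logits
  Mz <- matrix(c(50, -50, -50, 50), 2, 2)
  bd <- mapping_loss(Mz, NULL, S, G, d, mode = "plain")
  expect_equal(bd$density_term, 0, tolerance = 1e-9)
  expect_equal(bd$gene_axis_term, 4, tolerance = 1e-6)
  expect_equal(bd$voxel_axis_term, 2, tolerance = 1e-6)
  expect_equal(bd$total, -(4 + 2), tolerance = 1e-6)

  # uniform rows score strictly worse than the permutation
  bd_unif <- mapping_loss(matrix(0, 2, 2), NULL, S, G, d, mode = "plain")
  expect_gt(bd_unif$total, bd$total)

  # breakdown total is the weighted sum of its parts
  w <- c(0.7, 1.3, 0.4); lam <- 0.2
  Mz2 <- matrix(rnorm(6), 2, 3)
  S2 <- matrix(runif(8, 0.1, 2), 2, 4); G2 <- matrix(runif(12, 0.1, 2), 3, 4)
  bd2 <- mapping_loss(Mz2, rnorm(2), S2, G2, random_simplex(3),
                      mode = "filtered", n_target_cells = 1,
                      weights = w, lambda_r1 = lam)
  expect_equal(bd2$total,
               w[1] * bd2$density_term - w[2] * bd2$gene_axis_term -
                 w[3] * bd2$voxel_axis_term + lam * bd2$entropy_term +
                 bd2$count_term + bd2$filter_reg_term,
               tolerance = 1e-9)
  expect_error(mapping_loss(Mz2, rnorm(2), S2, G2, random_simplex(3),
                            mode = "filtered"), "n_target_cells")
})

test_that("loss values agree with the naive oracle on random instances", {
  withr::local_seed(10)
  for (i in 1:20) {
    S <- matrix(runif(12, 0.05, 3), 3, 4)
    G <- matrix(runif(12, 0.05, 3), 3, 4)
    d <- random_simplex(3)
    Mz <- matrix(rnorm(9), 3, 3); fz <- rnorm(3)
    w <- runif(3, 0.5, 1.5); lam <- runif(1, 0, 0.5)
    M <- softmax_rows(Mz); f <- sigmoid_filter(fz)
    bd_p <- mapping_loss(Mz, NULL, S, G, d, "plain", weights = w,
                         lambda_r1 = lam)
    expect_equal(bd_p$total, oracle_loss(M, NULL, S, G, d, weights = w,
                                         lambda = lam), tolerance = 1e-9)
    bd_f <- mapping_loss(Mz, fz, S, G, d, "filtered", n_target_cells = 2,
                         weights = w, lambda_r1 = lam)
    expect_equal(bd_f$total, oracle_loss(M, f, S, G, d, n_target = 2,
                                         weights = w, lambda = lam),
                 tolerance = 1e-9)
  }
})

test_that("analytic gradients match central finite differences", {
  withr::local_seed(12)
  S <- matrix(runif(12, 0.1, 2), 3, 4)
  G <- matrix(runif(12, 0.1, 2), 3, 4)
  d <- random_simplex(3)
  Mz <- matrix(rnorm(9), 3, 3); fz <- rnorm(3)
  for (mode in c("plain", "filtered")) {
    ev <- voxmap:::.loss_and_grad(Mz, fz, S, G, d, mode,
                                  n_target_cells = 2, weights = c(1, 1, 1),
                                  lambda_r1 = 0.3, want_grad = TRUE)
    num <- numeric_gradients(Mz, if (mode == "filtered") fz else NULL,
                             S, G, d, mode, n_target = 2, lambda = 0.3)
    expect_lt(max(abs(num$M - ev$grad_M_logits)) / max(abs(num$M)), 1e-4)
    if (mode == "filtered")
      expect_lt(max(abs(num$f - ev$grad_f_logits)) / max(abs(num$f)), 1e-4)
  }
})
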