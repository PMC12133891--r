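test_that("PCA scores match a dense covariance eigendecomposition oracle", {
  set.seed(11)
  x <- matrix(rnorm(12 * 40), 12, 40)
  rownames(x) <- paste0("d", 1:12)
  emb <- pca_embed(x, k = 5, standardize = FALSE)

  centered <- scale(x, center = TRUE, scale = FALSE)
  eg <- eigen(cov(centered), symmetric = TRUE)
  scores_oracle <- centered %*% eg$vectors[, 1:5]
  # align the oracle to the package's sign convention
  for (j in 1:5) {
    l <- eg$vectors[, j]
    if (l[which.max(abs(l))] < 0) scores_oracle[, j] <- -scores_oracle[, j]
  }
  got <- as.matrix(emb$coordinates[, -1])
  expect_lt(max(abs(got - scores_oracle)), 1e-8)

  var_oracle <- eg$values[1:5] / sum(eg$values)
  expect_equal(emb$variance_explained, var_oracle, tolerance = 1e-10)
  expect_true(all(diff(emb$variance_explained) <= 1e-12))
})

test_that("PCA reconstructs the centered input with all components", {
  set.seed(2)
  x <- matrix(rnorm(8 * 5), 8, 5)
  emb <- pca_embed(x, k = 5, standardize = FALSE)
  centered <- scale(x, center = TRUE, scale = FALSE)
  recon <- as.matrix(emb$coordinates[, -1]) %*% t(emb$loadings)
  expect_lt(max(abs(recon - centered)), 1e-8)
})

test_that("PCA sign rule and permutation invariance hold", {
  set.seed(3)
  x <- matrix(rnorm(10 * 6), 10, 6)
  emb <- pca_embed(x, k = 3)
  for (j in 1:3) {
    l <- emb$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  perm <- sample(nrow(x))
  emb_p <- pca_embed(x[perm, ], k = 3)
  expect_lt(max(abs(as.matrix(emb_p$coordinates[, -1]) -
                    as.matrix(emb$coordinates[perm, -1]))), 1e-8)
})

test_that("degenerate PCA inputs warn or error as specified", {
  two_same <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_error(pca_embed(two_same, k = 1),
               class = "dietwbm_degenerate_input")   # all columns constant
  x <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  expect_error(pca_embed(x, k = 4), class = "dietwbm_value_error")
  expect_error(pca_embed(x[1, , drop = FALSE], k = 1),
               class = "dietwbm_value_error")

  # rank-1 case: PC1 explains everything
  r1 <- pca_embed(rbind(c(1, 0), c(0, 1)), k = 1, standardize = FALSE)
  expect_equal(r1$variance_explained[1], 1, tolerance = 1e-12)

  with_const <- cbind(matrix(rnorm(12), 6, 2), 7)
  expect_warning(pca_embed(with_const, k = 2),
                 class = "dietwbm_constant_features")
})

test_that("t-SNE is reproducible for a fixed seed and validates inputs", {
  set.seed(5)
  x <- matrix(rnorm(12 * 5), 12, 5)
  e1 <- tsne_embed(x, seed = 1)
  e2 <- tsne_embed(x, seed = 1)
  expect_identical(e1$coordinates, e2$coordinates)
  expect_true(all(is.finite(as.matrix(e1$coordinates[, -1]))))
  expect_equal(dim(e1$coordinates), c(12, 3))

  e3 <- tsne_embed(x, seed = 2)
  expect_false(identical(e1$coordinates, e3$coordinates))

  expect_error(tsne_embed(x[1:3, ], seed = 1), class = "dietwbm_value_error")
  expect_error(tsne_embed(x, seed = 1, perplexity = 10),
               class = "dietwbm_value_error")
})

test_that("duplicated samples stay among the closest pairs in the embedding", {
  set.seed(6)
  base <- matrix(rnorm(9 * 4, sd = 3), 9, 4)
  x <- rbind(base, base[1, ])  # sample 10 duplicates sample 1
  emb <- tsne_embed(x, seed = 3)
  co <- as.matrix(emb$coordinates[, -1])
  d <- as.matrix(dist(co))
  dup_dist <- d[1, 10]
  offdiag <- d[upper.tri(d)]
  expect_lte(dup_dist, sort(offdiag)[3])
})

test_that("flux matrices are consistent, deterministic and model-checked", {
  suite <- study_suite()
  sols <- suite$male$solutions[1:3]
  fm <- flux_matrix(sols, "all_reactions")
  expect_equal(dim(fm), c(3, 1 + nrow(suite$male$model$reactions)))
  expect_equal(fm$diet, names(sols))

  pm <- flux_matrix(sols, "panel_reactions", panel = suite$male$panel)
  panel_ids <- unique(unlist(suite$male$panel[
    c("glucose_exchange", "tag_synthesis", "ldl_exchange",
      "hdl_exchange", "fao")]))
  expect_equal(ncol(pm) - 1, length(panel_ids))

  # identical diets produce identical rows (pFBA uniqueness upstream)
  dup <- list(a = sols[[1]], b = sols[[1]])
  fm2 <- flux_matrix(dup, "all_reactions")
  expect_equal(unlist(fm2[1, -1]), unlist(fm2[2, -1]))

  mixed <- list(a = sols[[1]], b = suite$female$solutions[[1]])
  expect_error(flux_matrix(mixed, "all_reactions"),
               class = "dietwbm_consistency_error")
  expect_error(flux_matrix(sols, "panel_reactions"),
               class = "dietwbm_value_error")
})
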