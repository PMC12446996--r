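test_that("filter_spots drops poor spots and undetected genes", {
  counts <- matrix(c(10, 10, 10,   # g1
                     10, 10,  0,   # g2
                      0,  0,  0),  # g3: detected nowhere after filtering
                   nrow = 3, byrow = TRUE)
  ds <- spot_dataset(counts, paste0("g", 1:3), paste0("S", 1:3))
  expect_message(f <- filter_spots(ds, min_counts = 15, min_genes = 2),
                 "removed")
  expect_equal(f$spot_ids, c("S1", "S2"))
  expect_equal(f$gene_ids, c("g1", "g2"))
  expect_error(suppressMessages(filter_spots(ds, min_counts = 1e6)),
               "all spots removed")
})

test_that("normalize_log matches the closed-form transform", {
  counts <- matrix(c(2, 0, 3, 5), 2, 2)
  ds <- spot_dataset(counts, c("g1", "g2"), c("S1", "S2"))
  x <- normalize_log(ds, scale_total = 100)
  expect_s3_class(x, "ExprMatrix")
  expect_equal(x$values["g1", "S1"], log1p(100 * 2 / 2))
  expect_equal(x$values["g2", "S2"], log1p(100 * 5 / 8))
  ds0 <- spot_dataset(matrix(c(1, 0), 1, 2), "g1", c("S1", "S2"))
  expect_error(normalize_log(ds0), "zero spot total")
})

test_that("pca_embed returns orthonormal loadings and score projections", {
  x <- toy_som_input(30L, 12L, seed = 4L)
  s <- pca_embed(x, n_components = 5L)
  expect_equal(dim(s), c(12L, 5L))
  expect_equal(rownames(s), colnames(x$values))
  rot <- attr(s, "rotation")
  expect_equal(crossprod(rot), diag(5), ignore_attr = TRUE, tolerance = 1e-10)
  z <- glandst:::scale_genes(x$values)
  expect_equal(unname(t(z) %*% rot), unname(unclass(s)[, 1:5]),
               tolerance = 1e-10)
  expect_equal(apply(s, 2, sd), attr(s, "sdev"), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_error(pca_embed(x, n_components = 13L), "exceeds")
})

test_that("pca_embed agrees with an eigendecomposition oracle on 6x6", {
  x <- toy_expr(withr::with_seed(9L, matrix(rnorm(36), 6, 6)))
  s <- pca_embed(x, n_components = 3L)
  z <- glandst:::scale_genes(x$values)
  ev <- eigen(stats::cov(t(z)), symmetric = TRUE)
  expect_equal(attr(s, "sdev")^2, ev$values[1:3], tolerance = 1e-8)
  for (j in 1:3)
    expect_equal(abs(stats::cor(s[, j], t(z) %*% ev$vectors[, j])), 1,
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("embed_2d is seed-deterministic and separates two blobs", {
  emb <- withr::with_seed(2L, rbind(matrix(rnorm(60, 0), 30, 2),
                                    matrix(rnorm(60, 12), 30, 2)))
  rownames(emb) <- paste0("S", 1:60)
  a <- embed_2d(emb, seed = 7L, n_neighbors = 10L)
  b <- embed_2d(emb, seed = 7L, n_neighbors = 10L)
  expect_identical(a, b)
  expect_equal(dim(a), c(60L, 2L))
  expect_equal(colnames(a), c("UMAP1", "UMAP2"))
  grp <- rep(1:2, each = 30)
  centers <- apply(a, 2, tapply, grp, mean)
  between <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  within <- mean(sqrt(rowSums((a - centers[grp, ])^2)))
  expect_gt(between, 2 * within)
})

test_that("snn_cluster recovers two well-separated blobs exactly", {
  emb <- withr::with_seed(3L, rbind(matrix(rnorm(80, 0), 40, 2),
                                    matrix(rnorm(80, 20), 40, 2)))
  rownames(emb) <- paste0("S", 1:80)
  cl <- snn_cluster(emb, k_neighbors = 20L, resolution = 0.5, seed = 1L)
  truth <- rep(1:2, each = 40)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(ari(cl, truth), 1)
  expect_equal(mclust::adjustedRandIndex(cl, truth), ari(cl, truth))
  expect_equal(names(cl), rownames(emb))
  expect_error(snn_cluster(emb, k_neighbors = 80L), "k_neighbors")
})

test_that("identical coordinates collapse to a single cluster", {
  emb <- matrix(1, 10, 2)
  rownames(emb) <- paste0("S", 1:10)
  cl <- snn_cluster(emb, k_neighbors = 4L)
  expect_equal(unname(cl), rep(1L, 10))
})

test_that("the clustering beats the singleton partition on modularity", {
  emb <- withr::with_seed(5L, rbind(matrix(rnorm(60, 0), 30, 2),
                                    matrix(rnorm(60, 20), 30, 2)))
  rownames(emb) <- paste0("S", 1:60)
  g <- glandst:::snn_graph(emb, 10L)
  cl <- snn_cluster(emb, k_neighbors = 10L)
  w <- igraph::E(g)$weight
  q_cl <- igraph::modularity(g, cl, weights = w)
  q_single <- igraph::modularity(g, seq_len(60), weights = w)
  expect_gt(q_cl, q_single)
})

test_that("wilcoxon_markers reproduces the exact small-sample p-value", {
  v <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  x <- toy_expr(v)
  labs <- stats::setNames(rep(c("a", "b"), each = 3), colnames(v))
  res <- wilcoxon_markers(x, labs, "a", "b", logfc_threshold = 0)
  expect_equal(res$p, stats::wilcox.test(1:3, 4:6, exact = TRUE)$p.value)
  expect_equal(res$p, exact_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$p, 0.1)
  expect_equal(res$direction, "down")
})

test_that("fully tied genes get p = 1 and the fold-change gate filters", {
  v <- rbind(tied = rep(2, 8),
             big = c(5, 5, 5, 5, 0, 0, 0, 0),
             tiny = c(1, 1, 1, 1, 1.01, 1.01, 1.01, 1.01))
  x <- toy_expr(v)
  labs <- stats::setNames(rep(c("a", "b"), each = 4), colnames(v))
  res0 <- wilcoxon_markers(x, labs, "a", "b", logfc_threshold = 0)
  expect_equal(res0$p[res0$gene == "tied"], 1)
  res <- wilcoxon_markers(x, labs, "a", "b", logfc_threshold = 0.1)
  expect_true("big" %in% res$gene)
  expect_false("tiny" %in% res$gene)
  expect_false("tied" %in% res$gene)
})

test_that("the normal approximation tracks the exact enumeration", {
  a <- withr::with_seed(11L, rnorm(9))
  b <- withr::with_seed(12L, rnorm(9, 0.8))
  v <- rbind(g1 = c(a, b))
  x <- toy_expr(v)
  labs <- stats::setNames(rep(c("a", "b"), each = 9), colnames(v))
  res <- wilcoxon_markers(x, labs, "a", "b", logfc_threshold = 0)
  expect_lt(abs(res$p - exact_wilcoxon_p(a, b)), 0.02)
})

test_that("adjusted p-values follow Benjamini-Hochberg over tested genes", {
  v <- withr::with_seed(8L, matrix(rnorm(20 * 10), 20, 10))
  v[1:5, 1:5] <- v[1:5, 1:5] + 3
  x <- toy_expr(v)
  labs <- stats::setNames(rep(c("a", "b"), each = 5), colnames(x$values))
  res <- wilcoxon_markers(x, labs, "a", "b", logfc_threshold = 0)
  expect_equal(res$p_adj, stats::p.adjust(res$p, method = "BH"))
  expect_true(all(res$p_adj >= res$p))
  expect_true(!is.unsorted(res$p))
})

test_that("marker results are invariant to spot-column permutation", {
  v <- withr::with_seed(13L, matrix(rnorm(12 * 8), 12, 8,
                                    dimnames = list(paste0("g", 1:12),
                                                    paste0("S", 1:8))))
  labs <- stats::setNames(rep(c("a", "b"), each = 4), colnames(v))
  perm <- withr::with_seed(14L, sample(8))
  r1 <- wilcoxon_markers(toy_expr(v), labs, "a", "b", logfc_threshold = 0)
  r2 <- wilcoxon_markers(toy_expr(v[, perm]), labs, "a", "b",
                         logfc_threshold = 0)
  expect_equal(r1, r2)
})
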