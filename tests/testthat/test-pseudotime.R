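test_that("a single-centroid backbone is the coordinate mean with no edges", {
  coords <- withr::with_seed(1L, matrix(rnorm(20), 10, 2))
  bb <- fit_principal_graph(coords, n_centroids = 1L)
  expect_equal(bb$centroids, matrix(colMeans(coords), 1, 2),
               ignore_attr = TRUE)
  expect_equal(nrow(bb$edges), 0L)
  expect_error(fit_principal_graph(coords, n_centroids = 11L), "exceeds")
  expect_error(fit_principal_graph(coords, n_centroids = 0L), ">= 1")
})

test_that("collinear points yield a chain backbone in coordinate order", {
  coords <- cbind(seq(0, 30, length.out = 60), 0)
  rownames(coords) <- paste0("S", 1:60)
  bb <- fit_principal_graph(coords, n_centroids = 6L, seed = 2L)
  ord <- order(bb$centroids[, 1])
  # a chain: every edge joins neighbors in sorted x-order
  pos <- match(seq_len(6), ord)
  expect_true(all(abs(pos[bb$edges$from] - pos[bb$edges$to]) == 1))
  expect_equal(sum(bb$edges$length),
               max(bb$centroids[, 1]) - min(bb$centroids[, 1]),
               tolerance = 1e-8)
})

test_that("the backbone tree is no longer than any spanning path", {
  coords <- withr::with_seed(3L, matrix(rnorm(80, sd = 4), 40, 2))
  bb <- fit_principal_graph(coords, n_centroids = 6L, seed = 1L)
  mst_len <- sum(bb$edges$length)
  d <- as.matrix(dist(bb$centroids))
  perms <- withr::with_seed(4L,
    replicate(50, sample(6), simplify = FALSE))
  path_len <- vapply(perms, function(p)
    sum(d[cbind(p[-6], p[-1])]), numeric(1))
  expect_true(all(mst_len <= path_len + 1e-10))
})

test_that("pseudotime starts at zero near the root cluster", {
  coords <- cbind(seq(0, 20, length.out = 80),
                  withr::with_seed(5L, rnorm(80, sd = 0.05)))
  rownames(coords) <- paste0("S", 1:80)
  bb <- fit_principal_graph(coords, n_centroids = 8L, seed = 1L)
  res <- assign_pseudotime(bb, coords, paste0("S", 1:10))
  expect_s3_class(res, "PseudotimeResult")
  expect_true(all(res$pt >= 0))
  expect_lt(min(res$pt[1:10]), 1.5)
  expect_equal(res$root, which.min(bb$centroids[, 1]))
  expect_error(assign_pseudotime(bb, coords, character(0)), "empty root")
  expect_error(assign_pseudotime(bb, coords, "nope"), "unknown root")
})

test_that("pseudotime orders collinear spots perfectly", {
  coords <- cbind(seq(0, 20, length.out = 80),
                  withr::with_seed(6L, rnorm(80, sd = 0.05)))
  rownames(coords) <- paste0("S", 1:80)
  bb <- fit_principal_graph(coords, n_centroids = 8L, seed = 1L)
  res <- assign_pseudotime(bb, coords, paste0("S", 1:10))
  expect_equal(stats::cor(res$pt, coords[, 1], method = "spearman"), 1,
               tolerance = 0.02)
})

test_that("pseudotime is homogeneous of degree one in the coordinates", {
  coords <- withr::with_seed(7L, matrix(rnorm(100, sd = 3), 50, 2))
  rownames(coords) <- paste0("S", 1:50)
  bb1 <- fit_principal_graph(coords, n_centroids = 6L, seed = 1L)
  bb3 <- fit_principal_graph(coords * 3, n_centroids = 6L, seed = 1L)
  r1 <- assign_pseudotime(bb1, coords, "S1")
  r3 <- assign_pseudotime(bb3, coords * 3, "S1")
  expect_equal(r3$pt, 3 * r1$pt, tolerance = 1e-8)
  expect_equal(r3$offset, 3 * r1$offset, tolerance = 1e-8)
})

test_that("an edgeless backbone yields zero pseudotime and radial offsets", {
  coords <- withr::with_seed(8L, matrix(rnorm(12), 6, 2))
  rownames(coords) <- paste0("S", 1:6)
  bb <- fit_principal_graph(coords, n_centroids = 1L)
  res <- assign_pseudotime(bb, coords, "S1")
  expect_true(all(res$pt == 0))
  expect_equal(res$offset,
               sqrt(rowSums((coords - rep(bb$centroids[1, ],
                                          each = 6))^2)),
               ignore_attr = TRUE)
})

# 100 staggered pulse genes over 40 spots: gene with midpoint m peaks at
# pseudotime m, ten genes per midpoint
staggered_pt_fixture <- function() {
  pt <- stats::setNames(1:40, paste0("S", 1:40))
  mids <- rep(seq(4, 36, length.out = 10), each = 10)
  v <- withr::with_seed(9L, {
    pulse <- outer(mids, pt, function(m, t) exp(-(t - m)^2 / 18))
    pulse + matrix(rnorm(length(pulse), 0, 0.01), nrow(pulse))
  })
  rownames(v) <- sprintf("g%03d", seq_len(100))
  colnames(v) <- names(pt)
  list(x = toy_expr(v), pt = pt, mids = mids)
}

test_that("pt_degs ranks monotone genes by association strength", {
  pt <- stats::setNames(1:20, paste0("S", 1:20))
  v <- rbind(up = 1:20, down = 20:1, flat = rep(1, 20),
             noisy = withr::with_seed(10L, rnorm(20)))
  colnames(v) <- names(pt)
  x <- toy_expr(v)
  tbl <- pt_degs(x, pt, n_top = 4L, n_bins = 10L)
  expect_equal(tbl$rho[tbl$gene == "up"], 1)
  expect_equal(tbl$rho[tbl$gene == "down"], -1)
  expect_equal(tbl$rho[tbl$gene == "flat"], 0)
  expect_equal(tbl$gene[1:2], c("down", "up"))  # ties in |rho| by gene id
  expect_equal(tbl$max_bin[tbl$gene == "up"], 10L)
  expect_equal(tbl$max_bin[tbl$gene == "down"], 1L)
  expect_equal(tbl$rank, 1:4)
  prof <- attr(tbl, "profiles")
  expect_equal(dim(prof), c(4L, 10L))
  tbl2 <- pt_degs(x, pt, n_top = 2L, n_bins = 10L)
  expect_equal(nrow(tbl2), 2L)
  expect_error(pt_degs(x, stats::setNames(rep(1, 20), names(pt))),
               "constant pseudotime")
  expect_error(pt_degs(x, pt[1:5]), "missing")
})

test_that("order_and_window cuts consecutive labeled windows", {
  fx <- staggered_pt_fixture()
  tbl <- pt_degs(fx$x, fx$pt, n_top = 100L, n_bins = 20L)
  out <- order_and_window(tbl, window_size = 10L)
  expect_equal(sort(unique(out$window)),
               sort(paste0("GS", 1:10)))
  expect_equal(as.vector(table(out$window)), rep(10L, 10))
  expect_true(!is.unsorted(out$max_bin))
  wp <- attr(out, "window_profiles")
  expect_equal(dim(wp), c(20L, 10L))
  out2 <- order_and_window(tbl[1:100, ], window_size = 50L)
  expect_equal(sort(unique(out2$window)), c("GS1", "GS2"))
})

test_that("window order recovers the planted activation order", {
  fx <- staggered_pt_fixture()
  tbl <- pt_degs(fx$x, fx$pt, n_top = 100L, n_bins = 20L)
  out <- order_and_window(tbl, window_size = 10L)
  planted_mid <- fx$mids[match(out$gene, sprintf("g%03d", seq_len(100)))]
  win_idx <- as.integer(sub("GS", "", out$window))
  expect_gt(stats::cor(win_idx, planted_mid, method = "spearman"), 0.95)
  # smoothed window maxima advance with the window index
  wp <- attr(out, "window_profiles")
  expect_true(!is.unsorted(apply(wp, 2, which.max)))
})

test_that("window portraits are grid images of window gene density", {
  fx <- staggered_pt_fixture()
  m <- train_som(fx$x, grid_rows = 4L, grid_cols = 4L, epochs = 5L,
                 var_keep = 1)
  tbl <- pt_degs(fx$x, fx$pt, n_top = 100L, n_bins = 20L)
  out <- order_and_window(tbl, window_size = 20L, model = m)
  wps <- attr(out, "window_portraits")
  expect_length(wps, 5L)
  expect_s3_class(wps[[1]], "Portrait")
  expect_equal(sum(unclass(wps[[1]])), 20)
})
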