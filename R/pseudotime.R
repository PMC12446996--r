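#' Fit a principal graph to a 2-D spot embedding
#'
#' Seeded k-means centroids joined by a Euclidean minimum spanning tree: a
#' deterministic, desk-scale backbone for ordering spots along a maturation
#' trajectory.
#'
#' @param coords spots x 2 coordinate matrix (e.g. from [embed_2d()]).
#' @param n_centroids number of backbone nodes.
#' @param seed integer seed for k-means.
#' @return a `backbone`: list with `centroids` (n_centroids x 2) and `edges`
#'   (data frame `from`, `to`, `length`).
#' @export
fit_principal_graph <- function(coords, n_centroids = 25L, seed = 1L) {
  coords <- as.matrix(coords)
  if (n_centroids < 1) stop("n_centroids must be >= 1")
  if (n_centroids > nrow(coords)) stop("n_centroids exceeds number of spots")
  centroids <- if (n_centroids == 1L) {
    matrix(colMeans(coords), 1, ncol(coords))
  } else {
    withr::with_seed(as.integer(seed),
      stats::kmeans(coords, centers = n_centroids, nstart = 10,
                    iter.max = 100)$centers)
  }
  edges <- if (n_centroids > 1L) {
    d <- as.matrix(stats::dist(centroids))
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    tree <- igraph::mst(g, weights = igraph::E(g)$weight)
    el <- igraph::as_edgelist(tree, names = FALSE)
    data.frame(from = el[, 1], to = el[, 2],
               length = igraph::E(tree)$weight)
  } else {
    data.frame(from = integer(0), to = integer(0), length = numeric(0))
  }
  structure(list(centroids = unname(centroids), edges = edges),
            class = "backbone")
}

backbone_graph <- function(backbone) {
  igraph::graph_from_data_frame(
    data.frame(from = backbone$edges$from, to = backbone$edges$to,
               weight = backbone$edges$length),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(backbone$centroids))))
}

#' Assign pseudotime from a root cluster
#'
#' The root is the backbone node nearest the root cluster's coordinate
#' medoid; each spot is projected orthogonally onto its nearest backbone
#' edge, and pseudotime is the tree geodesic distance from the root to the
#' projection point.
#'
#' @param backbone from [fit_principal_graph()].
#' @param coords spots x 2 coordinate matrix (rownames = spot ids).
#' @param root_cluster_spots non-empty vector of spot ids (or row indices)
#'   forming the root cluster.
#' @return a `PseudotimeResult`: list with `backbone`, `root` (node index),
#'   `pt` (named non-negative pseudotime per spot), `edge` (nearest edge
#'   index per spot) and `offset` (projection distance).
#' @export
assign_pseudotime <- function(backbone, coords, root_cluster_spots) {
  stopifnot(inherits(backbone, "backbone"))
  coords <- as.matrix(coords)
  if (length(root_cluster_spots) == 0L) stop("empty root set")
  ri <- if (is.character(root_cluster_spots)) {
    match(root_cluster_spots, rownames(coords))
  } else as.integer(root_cluster_spots)
  if (anyNA(ri)) stop("unknown root spot id")
  rc <- coords[ri, , drop = FALSE]
  dr <- as.matrix(stats::dist(rc))
  medoid <- rc[which.min(rowSums(dr)), ]
  cd <- sqrt(colSums((t(backbone$centroids) - medoid)^2))
  root <- which.min(cd)

  n <- nrow(coords)
  ne <- nrow(backbone$edges)
  if (ne == 0L) {
    pt <- rep(0, n)
    names(pt) <- rownames(coords)
    return(structure(list(backbone = backbone, root = root, pt = pt,
                          edge = rep(NA_integer_, n), offset = sqrt(
                            rowSums((coords - matrix(
                              backbone$centroids[1, ], n, ncol(coords),
                              byrow = TRUE))^2))),
                     class = "PseudotimeResult"))
  }
  droot <- as.vector(igraph::distances(backbone_graph(backbone),
                                       v = as.character(root)))

  best_d2 <- rep(Inf, n)
  best_edge <- integer(n)
  best_t <- numeric(n)
  for (e in seq_len(ne)) {
    u <- backbone$centroids[backbone$edges$from[e], ]
    v <- backbone$centroids[backbone$edges$to[e], ]
    uv <- v - u
    len2 <- sum(uv^2)
    t <- if (len2 == 0) rep(0, n) else
      pmin(pmax((sweep(coords, 2, u) %*% uv) / len2, 0), 1)
    proj <- matrix(u, n, length(u), byrow = TRUE) + as.vector(t) * matrix(
      uv, n, length(uv), byrow = TRUE)
    d2 <- rowSums((coords - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_edge[upd] <- e
    best_t[upd] <- t[upd]
  }
  len <- backbone$edges$length[best_edge]
  pt <- pmin(droot[backbone$edges$from[best_edge]] + best_t * len,
             droot[backbone$edges$to[best_edge]] + (1 - best_t) * len)
  names(pt) <- rownames(coords)
  structure(list(backbone = backbone, root = root, pt = pt,
                 edge = best_edge, offset = sqrt(best_d2)),
            class = "PseudotimeResult")
}

# Spearman rho of every gene against a vector, vectorized over rows;
# zero-variance genes get rho = 0
row_spearman <- function(values, y) {
  ry <- rank(y)
  rx <- matrixStats::rowRanks(values, ties.method = "average")
  rx_c <- rx - rowMeans(rx)
  ry_c <- ry - mean(ry)
  num <- rx_c %*% ry_c
  den <- sqrt(rowSums(rx_c^2) * sum(ry_c^2))
  rho <- as.vector(num) / den
  rho[!is.finite(rho)] <- 0
  rho
}

#' Rank pseudotime-associated genes
#'
#' Per-gene Spearman correlation with pseudotime; genes ranked by |rho| (ties
#' broken by gene id) and the top `n_top` kept. Each kept gene is smoothed by
#' a sliding-window mean over equal-count pseudotime bins.
#'
#' @param x an `ExprMatrix` restricted to the spots with pseudotime.
#' @param pt named pseudotime vector covering all spots of `x`.
#' @param n_top number of genes to keep (default 500).
#' @param n_bins number of equal-count pseudotime bins (default 20).
#' @param smooth_window sliding-window width in bins.
#' @return a `PTGeneTable` data frame: `gene`, `rho`, `p`, `rank`, `max_bin`
#'   (bin of the smoothed maximum); attribute `profiles` holds the smoothed
#'   genes x bins profile matrix, attribute `bin_pt` the mean pseudotime per
#'   bin.
#' @export
pt_degs <- function(x, pt, n_top = 500L, n_bins = 20L, smooth_window = 3L) {
  stopifnot(inherits(x, "ExprMatrix"))
  spots <- colnames(x$values)
  if (!all(spots %in% names(pt))) stop("pseudotime missing for some spots")
  pt <- pt[spots]
  if (stats::sd(pt) == 0) stop("constant pseudotime")
  v <- x$values
  rho <- row_spearman(v, pt)
  n <- length(pt)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  ord <- order(-abs(rho), rownames(v))
  keep <- ord[seq_len(min(n_top, length(ord)))]

  n_bins <- min(n_bins, n)
  bin <- ceiling(rank(pt, ties.method = "first") / (n / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  means <- t(rowsum(t(v[keep, , drop = FALSE]), group = bin)) /
    matrix(counts, length(keep), n_bins, byrow = TRUE)
  half <- (smooth_window - 1) %/% 2
  sm <- means
  for (b in seq_len(n_bins)) {
    w <- max(1, b - half):min(n_bins, b + half)
    sm[, b] <- rowMeans(means[, w, drop = FALSE])
  }
  max_bin <- max.col(sm, ties.method = "first")

  tbl <- data.frame(gene = rownames(v)[keep], rho = rho[keep],
                    p = p[keep], rank = seq_along(keep), max_bin = max_bin)
  rownames(sm) <- tbl$gene
  attr(tbl, "profiles") <- sm
  attr(tbl, "bin_pt") <- as.vector(rowsum(pt, bin) / counts)
  class(tbl) <- c("PTGeneTable", "data.frame")
  tbl
}

#' Order pseudotime genes and cut consecutive windows
#'
#' Genes are sorted by the bin of their smoothed maximum (ties by rho sign,
#' increasing genes later, then gene id) and cut into consecutive blocks of
#' `window_size` labeled GS1, GS2, ...; per-window mean profiles (and, when a
#' SOM model is supplied, per-window gene-frequency portraits) are attached.
#'
#' @param tbl a `PTGeneTable` from [pt_degs()].
#' @param window_size genes per window (default 50).
#' @param model optional `SOMModel` for window portraits.
#' @return the reordered `PTGeneTable` with a `window` column; attributes
#'   `profiles` (reordered), `window_profiles` (bins x windows matrix of
#'   window-mean profiles) and optionally `window_portraits` (list of
#'   `Portrait`s showing each window's gene density on the grid).
#' @export
order_and_window <- function(tbl, window_size = 50L, model = NULL) {
  stopifnot(inherits(tbl, "PTGeneTable"))
  if (nrow(tbl) == 0L) stop("empty table")
  profiles <- attr(tbl, "profiles")
  ord <- order(tbl$max_bin, sign(tbl$rho), tbl$gene)
  out <- tbl[ord, , drop = FALSE]
  profiles <- profiles[ord, , drop = FALSE]
  nw <- ceiling(nrow(out) / window_size)
  out$window <- paste0("GS", ceiling(seq_len(nrow(out)) / window_size))
  wf <- factor(out$window, levels = paste0("GS", seq_len(nw)))
  wp <- t(rowsum(profiles, group = wf) /
            as.vector(table(wf)))  # bins x windows
  colnames(wp) <- levels(wf)
  rownames(out) <- NULL
  attr(out, "profiles") <- profiles
  attr(out, "bin_pt") <- attr(tbl, "bin_pt")
  attr(out, "window_profiles") <- wp
  if (!is.null(model)) {
    attr(out, "window_portraits") <- lapply(levels(wf), function(w) {
      genes <- intersect(out$gene[out$window == w],
                         names(model$gene_assignment))
      freq <- tabulate(model$gene_assignment[genes],
                       model$grid_rows * model$grid_cols)
      new_portrait(matrix(freq, model$grid_rows, model$grid_cols),
                   subject = w)
    })
  }
  class(out) <- c("PTGeneTable", "data.frame")
  out
}
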