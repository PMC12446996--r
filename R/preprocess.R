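#' Filter low-quality spots
#'
#' Keeps spots with at least `min_counts` total counts and at least
#' `min_genes` detected genes; genes detected in no remaining spot are
#' dropped.
#'
#' @param ds a [spot_dataset()].
#' @param min_counts,min_genes non-negative thresholds.
#' @return the filtered `SpotDataset`.
#' @export
filter_spots <- function(ds, min_counts = 0L, min_genes = 0L) {
  stopifnot(inherits(ds, "SpotDataset"), min_counts >= 0, min_genes >= 0)
  totals <- Matrix::colSums(ds$counts)
  detected <- Matrix::colSums(ds$counts > 0)
  keep_spots <- which(totals >= min_counts & detected >= min_genes)
  if (length(keep_spots) == 0L) stop("all spots removed by filtering")
  sub <- subset_spots(ds, spots = keep_spots)
  keep_genes <- which(Matrix::rowSums(sub$counts) > 0)
  sub <- subset_spots(sub, genes = keep_genes)
  message(sprintf("filter_spots: removed %d/%d spots and %d/%d genes",
                  length(ds$spot_ids) - length(keep_spots),
                  length(ds$spot_ids),
                  length(ds$gene_ids) - length(keep_genes),
                  length(ds$gene_ids)))
  sub
}

#' Library-size normalization and log transform
#'
#' `value = ln(1 + scale_total * count / spot_total)` — the de-facto standard
#' log-normalization of spot transcriptomes.
#'
#' @param ds a [spot_dataset()] with no all-zero spots.
#' @param scale_total target total per spot.
#' @return an `ExprMatrix`: list with dense `values` (genes x spots) and the
#'   normalization provenance (`scale_total`, `pseudocount`).
#' @export
normalize_log <- function(ds, scale_total = 1e4) {
  stopifnot(inherits(ds, "SpotDataset"))
  totals <- Matrix::colSums(ds$counts)
  if (any(totals == 0)) stop("zero spot total; run filter_spots first")
  v <- as.matrix(ds$counts)
  v <- log1p(scale_total * sweep(v, 2, totals, "/"))
  structure(list(values = v, scale_total = scale_total, pseudocount = 1),
            class = "ExprMatrix")
}

# gene-wise z-score with clipping; zero-variance genes map to 0
scale_genes <- function(values, clip = 10) {
  mu <- rowMeans(values)
  sd <- matrixStats::rowSds(values)
  sd[sd == 0] <- 1
  z <- (values - mu) / sd
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}

#' PCA embedding of spots
#'
#' Genes are centered and unit-scaled (clipped at +/-10) before the
#' decomposition so high-mean genes do not dominate.
#'
#' @param x an `ExprMatrix`.
#' @param n_components number of components to keep.
#' @return spots x n_components score matrix; attributes `sdev` (component
#'   standard deviations) and `rotation` (orthonormal gene loadings).
#' @export
pca_embed <- function(x, n_components = 30L) {
  stopifnot(inherits(x, "ExprMatrix"))
  if (n_components < 1) stop("n_components must be >= 1")
  v <- x$values
  if (n_components > min(dim(v)))
    stop("n_components exceeds min(genes, spots)")
  z <- scale_genes(v)
  p <- stats::prcomp(t(z), center = FALSE, scale. = FALSE,
                     rank. = n_components)
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- colnames(v)
  attr(scores, "sdev") <- p$sdev[seq_len(n_components)]
  attr(scores, "rotation") <- p$rotation[, seq_len(n_components),
                                         drop = FALSE]
  scores
}

#' Nonlinear 2-D embedding (UMAP)
#'
#' Deterministic under a fixed seed; used for visualization and as the
#' pseudotime substrate.
#'
#' @param embedding spots x k numeric matrix (e.g. from [pca_embed()]).
#' @param seed integer RNG seed.
#' @param n_neighbors neighborhood size (capped at n - 1).
#' @param min_dist UMAP minimum distance.
#' @return spots x 2 coordinate matrix.
#' @export
embed_2d <- function(embedding, seed = 1L, n_neighbors = 15L,
                     min_dist = 0.3) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n < 3L) stop("need at least 3 spots")
  nb <- min(n_neighbors, n - 1L)
  coords <- withr::with_seed(as.integer(seed),
    uwot::umap(embedding, n_neighbors = nb, min_dist = min_dist,
               n_threads = 1, n_sgd_threads = 0))
  rownames(coords) <- rownames(embedding)
  colnames(coords) <- c("UMAP1", "UMAP2")
  coords
}

#' Shared-nearest-neighbor modularity clustering
#'
#' Builds the k-nearest-neighbor graph in embedding space (neighbor sets
#' include the spot itself), weights each kNN edge by the Jaccard overlap of
#' the two neighbor sets, prunes zero weights, and maximizes modularity by
#' Louvain iteration at the given resolution. Labels are consecutive integers
#' ordered by decreasing cluster size.
#'
#' @param embedding spots x k numeric matrix.
#' @param k_neighbors neighborhood size (must be < number of spots).
#' @param resolution modularity resolution parameter.
#' @param seed integer RNG seed for the Louvain vertex order.
#' @return integer vector of cluster labels, named by the embedding rownames.
#' @export
snn_cluster <- function(embedding, k_neighbors = 20L, resolution = 0.8,
                        seed = 1L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n == 0L) stop("empty embedding")
  if (k_neighbors >= n) stop("k_neighbors must be < number of spots")
  g <- snn_graph(embedding, k_neighbors)
  cl <- withr::with_seed(as.integer(seed),
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relabel[as.character(memb)])
  names(out) <- rownames(embedding)
  out
}

# SNN graph: kNN edges weighted by Jaccard overlap of neighbor sets
snn_graph <- function(embedding, k_neighbors) {
  n <- nrow(embedding)
  k <- k_neighbors + 1L  # neighbor sets include self
  nn <- RANN::nn2(embedding, k = min(k, n))$nn.idx
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nn)),
                            j = as.vector(nn), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)                   # |N(i) & N(j)|
  adj <- ((A + Matrix::t(A)) > 0) * 1               # kNN edge mask (symmetric)
  s <- shared * adj
  s <- methods::as(methods::as(s, "generalMatrix"), "TsparseMatrix")
  keep <- s@i < s@j
  i <- s@i[keep] + 1L; j <- s@j[keep] + 1L; sh <- s@x[keep]
  w <- sh / (2 * ncol(nn) - sh)                     # Jaccard
  pos <- w > 0
  igraph::graph_from_data_frame(
    data.frame(from = i[pos], to = j[pos], weight = w[pos]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Wilcoxon rank-sum marker detection between two spot groups
#'
#' Per gene: two-sided Mann-Whitney p (exact when both groups have at most 8
#' spots and no ties, normal approximation with tie correction otherwise);
#' log2 fold change computed on expm1-back-transformed group means with
#' pseudocount 1. Genes with |log2FC| below `logfc_threshold` are excluded
#' before Benjamini-Hochberg adjustment over the remaining genes.
#'
#' @param x an `ExprMatrix` (log-normalized values).
#' @param labels named character/integer vector of spot labels.
#' @param groupA,groupB label value(s) defining the two groups.
#' @param logfc_threshold minimum |log2FC| gate (default 0.1).
#' @return data frame (class `DEGResult`) with columns `gene`, `log2FC`,
#'   `mean_A`, `mean_B`, `p`, `p_adj`, `direction` (up/down in group A),
#'   sorted by p.
#' @export
wilcoxon_markers <- function(x, labels, groupA, groupB,
                             logfc_threshold = 0.1) {
  stopifnot(inherits(x, "ExprMatrix"))
  spots <- colnames(x$values)
  if (is.null(names(labels))) names(labels) <- spots
  if (length(intersect(groupA, groupB)) > 0) stop("overlapping groups")
  sA <- intersect(spots, names(labels)[labels %in% groupA])
  sB <- intersect(spots, names(labels)[labels %in% groupB])
  if (length(sA) == 0L) stop("group not found in labels: ",
                             paste(groupA, collapse = ","))
  if (length(sB) == 0L) stop("group not found in labels: ",
                             paste(groupB, collapse = ","))
  vA <- x$values[, sA, drop = FALSE]
  vB <- x$values[, sB, drop = FALSE]
  mA <- rowMeans(expm1(vA))
  mB <- rowMeans(expm1(vB))
  log2fc <- log2((mA + 1) / (mB + 1))
  pass <- which(abs(log2fc) >= logfc_threshold)
  p <- vapply(pass, function(g) {
    wilcoxon_p(vA[g, ], vB[g, ])
  }, numeric(1))
  res <- data.frame(gene = rownames(x$values)[pass],
                    log2FC = log2fc[pass],
                    mean_A = mA[pass], mean_B = mB[pass],
                    p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    direction = ifelse(log2fc[pass] >= 0, "up", "down"))
  res <- res[order(res$p, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("DEGResult", "data.frame")
  res
}

# two-sided Mann-Whitney p: exact when both groups <= 8 and tie-free,
# normal approximation with tie correction otherwise
wilcoxon_p <- function(a, b) {
  if (length(unique(c(a, b))) == 1L) return(1)  # fully tied: no evidence
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact)$p.value)
}
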