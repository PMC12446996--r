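#' Overrepresentation analysis (hypergeometric test)
#'
#' For each gene set, tests whether the gene list overlaps it more than
#' expected under hypergeometric sampling from the universe:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' universe size, `K` the set size within the universe, `n` the list size and
#' `k` the observed overlap. Benjamini-Hochberg correction is applied over
#' all tested sets; sets with no universe overlap are skipped.
#'
#' @param gene_list character vector, a subset of `universe`.
#' @param universe character vector of background genes.
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]).
#' @return an `EnrichmentResult` data frame: `set`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, `genes` (comma-separated overlap), sorted by p.
#' @export
ora <- function(gene_list, universe, gene_sets) {
  gene_list <- unique(as.character(gene_list))
  universe <- unique(as.character(universe))
  if (length(gene_list) == 0L) stop("empty gene_list")
  if (length(universe) == 0L) stop("empty universe")
  if (!all(gene_list %in% universe)) stop("gene_list must be within universe")
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    if (K == 0L) return(NULL)
    hits <- intersect(gene_list, set)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(hits), collapse = ","))
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      genes = character(0))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set), c("set", "k", "K", "n", "N", "p", "q",
                                      "genes")]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Functional gene-set coloring of the tissue map
#'
#' Per-spot mean normalized expression of a gene set's present genes, with
#' lattice positions for heatmap rendering; optionally also the per-cluster
#' mean (the cell-type x gene-set relatedness summary).
#'
#' @param ds the [spot_dataset()] providing positions (and labels).
#' @param x an `ExprMatrix`.
#' @param gene_set character vector; at least one member must be present.
#' @param coords optional spots x 2 embedding coordinates to attach.
#' @return data frame `spot_id`, `array_row`, `array_col`, `score` (plus
#'   embedding columns when `coords` given); attribute `cluster_means` holds
#'   the per-cluster mean score when the dataset carries labels.
#' @export
functional_coloring <- function(ds, x, gene_set, coords = NULL) {
  stopifnot(inherits(ds, "SpotDataset"), inherits(x, "ExprMatrix"))
  genes <- intersect(gene_set, rownames(x$values))
  if (length(genes) == 0L) stop("no set gene present in the matrix")
  score <- colMeans(x$values[genes, , drop = FALSE])
  spots <- colnames(x$values)
  pos <- ds$positions[match(spots, ds$positions$spot_id), ]
  out <- data.frame(spot_id = spots, array_row = pos$array_row,
                    array_col = pos$array_col, score = unname(score))
  if (!is.null(coords)) {
    ci <- match(spots, rownames(coords))
    out$dim1 <- coords[ci, 1]
    out$dim2 <- coords[ci, 2]
  }
  if (!is.null(ds$labels)) {
    lab <- ds$labels[spots]
    attr(out, "cluster_means") <-
      tapply(score, lab, mean)[sort(unique(lab))]
  }
  out
}
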