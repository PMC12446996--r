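#' Venn partition of two gene lists
#'
#' @param listA,listB deduplicated character vectors.
#' @return list with `shared`, `uniqueA`, `uniqueB` (a true partition of the
#'   union: `|shared| + |uniqueA| = |A|`, and symmetrically for B).
#' @export
venn_lists <- function(listA, listB) {
  listA <- unique(as.character(listA))
  listB <- unique(as.character(listB))
  list(shared = intersect(listA, listB),
       uniqueA = setdiff(listA, listB),
       uniqueB = setdiff(listB, listA))
}

#' Assign genes to maturation stages by mean expression
#'
#' Each gene is assigned the stage with the highest mean normalized
#' expression across that stage's spots; exact ties go to the earlier stage
#' in the declared order. By default each spot's gene-wide mean is subtracted
#' first: in log space the library-composition dilution of a spot is a common
#' additive shift, and without removing it genes that are off everywhere
#' drift toward the stage with the least active transcriptome rather than
#' the stage where they rise.
#'
#' @param genes character vector of genes to assign.
#' @param x an `ExprMatrix`.
#' @param labels named vector of spot stage labels.
#' @param ordered_stages ordered character vector of stage names (earliest
#'   first); every stage must have at least one labeled spot.
#' @param center_spots subtract each spot's mean over genes first (default
#'   `TRUE`).
#' @return named factor (levels = `ordered_stages`) mapping gene to stage.
#' @export
assign_stage <- function(genes, x, labels, ordered_stages,
                         center_spots = TRUE) {
  stopifnot(inherits(x, "ExprMatrix"))
  if (length(genes) == 0L) stop("no genes to assign")
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing)) stop("gene absent from matrix: ", missing[1])
  v <- x$values
  if (center_spots) v <- sweep(v, 2, Matrix::colMeans(v))
  spots <- colnames(v)
  if (is.null(names(labels))) names(labels) <- spots
  stage_means <- sapply(ordered_stages, function(s) {
    sp <- intersect(spots, names(labels)[labels == s])
    if (length(sp) == 0L) stop("stage with zero spots: ", s)
    rowMeans(v[genes, sp, drop = FALSE])
  })
  stage_means <- matrix(stage_means, nrow = length(genes),
                        dimnames = list(genes, ordered_stages))
  # max.col with ties.method = "first" implements the earlier-stage tie rule
  idx <- max.col(stage_means, ties.method = "first")
  stats::setNames(factor(ordered_stages[idx], levels = ordered_stages), genes)
}

#' Stage-flow (Sankey) counts of shared genes
#'
#' Counts shared genes per (stage in A, stage in B) cell; the contingency
#' table behind a Sankey flow diagram between two glands' maturation stages.
#'
#' @param shared character vector of shared genes.
#' @param stageA,stageB stage assignments from [assign_stage()], covering all
#'   shared genes.
#' @return a `SankeyTable`: list with `counts` (ordered stages A x ordered
#'   stages B integer matrix), `rowsums`, `colsums`, `total`.
#' @export
sankey_counts <- function(shared, stageA, stageB) {
  if (!all(shared %in% names(stageA)) || !all(shared %in% names(stageB)))
    stop("unassigned shared gene")
  tab <- table(A = stageA[shared], B = stageB[shared])
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  structure(list(counts = counts, rowsums = rowSums(counts),
                 colsums = colSums(counts), total = sum(counts)),
            class = "SankeyTable")
}

#' @export
print.SankeyTable <- function(x, ...) {
  cat("SankeyTable (", x$total, "shared genes )\n")
  print(x$counts)
  invisible(x)
}

#' Cross-gland differential expression with volcano table
#'
#' Wilcoxon markers between two gland cell groups plus the volcano inputs
#' (log2FC, -log10 adjusted p) and the up/down gene sets at a significance
#' cutoff.
#'
#' @inheritParams wilcoxon_markers
#' @param sig_cutoff adjusted-p significance cutoff for the up/down sets.
#' @return list with `degs` (the `DEGResult`), `volcano` (gene, log2FC,
#'   neg_log10_p_adj, significant), `up`, `down` (character vectors).
#' @export
cross_gland_degs <- function(x, labels, groupA, groupB,
                             logfc_threshold = 0.1, sig_cutoff = 0.05) {
  degs <- wilcoxon_markers(x, labels, groupA, groupB, logfc_threshold)
  volcano <- data.frame(gene = degs$gene, log2FC = degs$log2FC,
                        neg_log10_p_adj = -log10(pmax(degs$p_adj, 1e-300)),
                        significant = degs$p_adj < sig_cutoff)
  list(degs = degs, volcano = volcano,
       up = degs$gene[degs$p_adj < sig_cutoff & degs$log2FC > 0],
       down = degs$gene[degs$p_adj < sig_cutoff & degs$log2FC < 0])
}

#' Joint embedding of two datasets over shared genes
#'
#' Both datasets are restricted to their shared genes, log-normalized, and
#' each gene is centered and unit-scaled per dataset; spots are then
#' concatenated and embedded by joint PCA followed by UMAP. The per-spot
#' dataset tag is retained so split views can be produced.
#'
#' @param dsA,dsB [spot_dataset()] objects with at least `min_shared` genes
#'   in common.
#' @param n_components PCA components for the joint decomposition.
#' @param seed seed for the 2-D embedding.
#' @param min_shared minimum shared-gene count.
#' @return data frame: `spot_id`, `dataset` ("A"/"B"), `label` (cluster tag
#'   when present), `UMAP1`, `UMAP2`.
#' @export
integrate_datasets <- function(dsA, dsB, n_components = 30L, seed = 1L,
                               min_shared = 50L) {
  stopifnot(inherits(dsA, "SpotDataset"), inherits(dsB, "SpotDataset"))
  shared <- intersect(dsA$gene_ids, dsB$gene_ids)
  if (length(shared) < min_shared)
    stop("shared gene set too small: ", length(shared))
  za <- scale_genes(normalize_log(subset_spots(dsA, genes = shared))$values)
  zb <- scale_genes(normalize_log(subset_spots(dsB, genes = shared))$values)
  joint <- cbind(za, zb)
  colnames(joint) <- c(paste0("A_", dsA$spot_ids), paste0("B_", dsB$spot_ids))
  xm <- structure(list(values = joint, scale_total = NA, pseudocount = 1),
                  class = "ExprMatrix")
  k <- min(n_components, min(dim(joint)))
  emb <- pca_embed(xm, k)
  coords <- embed_2d(emb, seed = seed)
  lab <- c(if (is.null(dsA$labels)) rep(NA, length(dsA$spot_ids))
           else unname(dsA$labels),
           if (is.null(dsB$labels)) rep(NA, length(dsB$spot_ids))
           else unname(dsB$labels))
  data.frame(spot_id = c(dsA$spot_ids, dsB$spot_ids),
             dataset = rep(c("A", "B"),
                           c(length(dsA$spot_ids), length(dsB$spot_ids))),
             label = lab, UMAP1 = coords[, 1], UMAP2 = coords[, 2])
}
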