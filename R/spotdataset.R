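#' Spot-by-gene dataset with lattice positions
#'
#' The common currency of the pipeline: a genes x spots count matrix together
#' with spot positions on the capture lattice and optional cluster labels.
#'
#' @param counts genes x spots matrix of non-negative integer counts; coerced
#'   to a sparse [`Matrix::dgCMatrix`].
#' @param gene_ids unique character vector, one per matrix row.
#' @param spot_ids unique character vector, one per matrix column.
#' @param positions data frame with one row per spot and columns
#'   `spot_id`, `in_tissue`, `array_row`, `array_col`, `pxl_row`, `pxl_col`.
#'   If `NULL`, a degenerate all-zero lattice is used (with a warning).
#' @param labels optional named character vector mapping spot ids to cluster
#'   names.
#'
#' @return An object of class `SpotDataset`: a list with elements `counts`,
#'   `gene_ids`, `spot_ids`, `positions`, `labels`.
#' @export
spot_dataset <- function(counts, gene_ids, spot_ids, positions = NULL,
                         labels = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (nrow(counts) != length(gene_ids))
    stop("nrow(counts) != length(gene_ids)")
  if (ncol(counts) != length(spot_ids))
    stop("ncol(counts) != length(spot_ids)")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(spot_ids)) stop("duplicate spot ids")
  if (is.null(positions)) {
    warning("no positions supplied; using a degenerate 0 lattice")
    positions <- data.frame(spot_id = spot_ids, in_tissue = 1L,
                            array_row = 0L, array_col = 0L,
                            pxl_row = 0, pxl_col = 0)
  }
  need <- c("spot_id", "in_tissue", "array_row", "array_col",
            "pxl_row", "pxl_col")
  if (!all(need %in% names(positions)))
    stop("positions must have columns: ", paste(need, collapse = ", "))
  if (!all(spot_ids %in% positions$spot_id))
    stop("positions must cover all spots")
  positions <- positions[match(spot_ids, positions$spot_id), , drop = FALSE]
  rownames(positions) <- NULL
  dimnames(counts) <- list(gene_ids, spot_ids)
  if (!is.null(labels)) {
    labels <- labels[spot_ids]
    names(labels) <- spot_ids
  }
  structure(list(counts = counts, gene_ids = gene_ids, spot_ids = spot_ids,
                 positions = positions, labels = labels),
            class = "SpotDataset")
}

#' @export
print.SpotDataset <- function(x, ...) {
  cat(sprintf("SpotDataset: %d genes x %d spots\n",
              length(x$gene_ids), length(x$spot_ids)))
  if (!is.null(x$labels))
    cat("labels:", paste(names(table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.SpotDataset <- function(x) dim(x$counts)

#' Subset a SpotDataset by genes and/or spots
#'
#' @param ds a `SpotDataset`.
#' @param genes character or index vector of genes to keep (default all).
#' @param spots character or index vector of spots to keep (default all).
#' @return the subsetted `SpotDataset`.
#' @export
subset_spots <- function(ds, genes = NULL, spots = NULL) {
  stopifnot(inherits(ds, "SpotDataset"))
  gi <- if (is.null(genes)) seq_along(ds$gene_ids) else genes
  si <- if (is.null(spots)) seq_along(ds$spot_ids) else spots
  if (is.character(gi)) gi <- match(gi, ds$gene_ids)
  if (is.character(si)) si <- match(si, ds$spot_ids)
  if (anyNA(gi) || anyNA(si)) stop("unknown gene or spot id in subset")
  spot_dataset(ds$counts[gi, si, drop = FALSE],
               ds$gene_ids[gi], ds$spot_ids[si],
               ds$positions[si, , drop = FALSE],
               if (is.null(ds$labels)) NULL else ds$labels[si])
}
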