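#' Read a Visium-style bundle into a SpotDataset
#'
#' Expects `matrix.mtx` (MatrixMarket triplets, 1-based indices, genes x
#' spots), `features.tsv` and `barcodes.tsv`; `tissue_positions.csv`
#' (barcode,in_tissue,array_row,array_col,pxl_row,pxl_col) is optional —
#' without it positions default to a degenerate 0 lattice with a warning.
#' When positions are present, spots are restricted to `in_tissue == 1`.
#'
#' @param dir directory containing the bundle.
#' @return a [spot_dataset()].
#' @export
read_visium_bundle <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  bc <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feat, bc))
    if (!file.exists(f)) stop("missing bundle file: ", f)
  counts <- Matrix::readMM(mtx)
  features <- utils::read.delim(feat, header = FALSE,
                                stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(bc, header = FALSE,
                                stringsAsFactors = FALSE)
  gene_ids <- as.character(features[[1]])
  spot_ids <- as.character(barcodes[[1]])
  if (nrow(counts) != length(gene_ids))
    stop("matrix declares ", nrow(counts), " genes but features.tsv lists ",
         length(gene_ids))
  if (ncol(counts) != length(spot_ids))
    stop("matrix declares ", ncol(counts), " spots but barcodes.tsv lists ",
         length(spot_ids))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in features.tsv")
  if (anyDuplicated(spot_ids)) stop("duplicate spot ids in barcodes.tsv")
  pos_file <- file.path(dir, "tissue_positions.csv")
  positions <- NULL
  if (file.exists(pos_file)) {
    pos <- utils::read.csv(pos_file, stringsAsFactors = FALSE)
    names(pos)[1] <- "spot_id"
    positions <- pos[, c("spot_id", "in_tissue", "array_row", "array_col",
                         "pxl_row", "pxl_col")]
  }
  ds <- spot_dataset(counts, gene_ids, spot_ids, positions)
  keep <- which(ds$positions$in_tissue == 1L)
  if (length(keep) < length(ds$spot_ids)) ds <- subset_spots(ds, spots = keep)
  ds
}

#' Write a SpotDataset as a Visium-style bundle
#'
#' Emits `matrix.mtx` with an integer MatrixMarket header and 1-based triplet
#' indices, `features.tsv`, `barcodes.tsv` and `tissue_positions.csv`; cluster
#' labels, when present, go to `labels.tsv` (spot_id, label).
#'
#' @param ds a [spot_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_visium_bundle <- function(ds, dir) {
  stopifnot(inherits(ds, "SpotDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(ds$counts, "TsparseMatrix")
  con <- file(file.path(dir, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  writeLines(sprintf("%d %d %d", m@i + 1L, m@j + 1L, as.integer(m@x)), con)
  close(con)
  utils::write.table(data.frame(id = ds$gene_ids, name = ds$gene_ids,
                                type = "Gene Expression"),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(ds$spot_ids, file.path(dir, "barcodes.tsv"))
  pos <- ds$positions
  names(pos)[1] <- "barcode"
  utils::write.csv(pos, file.path(dir, "tissue_positions.csv"),
                   quote = FALSE, row.names = FALSE)
  if (!is.null(ds$labels))
    utils::write.table(data.frame(spot_id = names(ds$labels),
                                  label = unname(ds$labels)),
                       file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member genes. Duplicate
#' genes within a line are removed; sets left empty are dropped with a
#' warning; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("GMT line with fewer than 3 fields: line ", which(short)[1])
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set name: ",
                              nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty gene set(s)")
    sets <- sets[!empty]
  }
  sets
}

#' Write analysis results to a directory
#'
#' Data frames are written as TSV with a header; matrices (portraits, grids,
#' Sankey tables) as plain numeric grid TSVs without headers; a
#' `manifest.json` records the supplied config (including seeds) and the
#' package version.
#'
#' @param outdir output directory (created if needed).
#' @param ... named objects to write (`name` becomes `name.tsv`).
#' @param config optional named list recorded in the manifest.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(outdir, ..., config = NULL) {
  objs <- list(...)
  if (length(objs) && is.null(names(objs))) stop("objects must be named")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(objs)) {
    x <- objs[[nm]]
    path <- file.path(outdir, paste0(nm, ".tsv"))
    if (inherits(x, "Portrait")) {
      x <- unclass(x)
      attr(x, "subject") <- NULL
    }
    if (is.matrix(x)) {
      utils::write.table(x, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    } else if (is.data.frame(x)) {
      utils::write.table(x, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      utils::write.table(data.frame(value = x), path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    written <- c(written, path)
  }
  manifest <- list(
    package = "glandst",
    version = as.character(utils::packageVersion("glandst")),
    config = config,
    files = basename(written))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, mpath))
}

#' Read a flat key-value config file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are parsed
#' as numeric where possible, else kept as strings.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line")
  keys <- trimws(vapply(kv, `[[`, "", 2L))
  vals <- trimws(vapply(kv, `[[`, "", 3L))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  stats::setNames(out, keys)
}
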