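#' Train a batch self-organizing map over genes
#'
#' Reduces the gene space to a grid of metagenes: each SOM node holds a
#' codebook vector (its profile across spots), and every gene is assigned to
#' its best-matching node (Euclidean distance). Training is batch: per epoch
#' all genes are assigned, then every node is set to the Gaussian
#' neighborhood-kernel-weighted mean of the assigned gene profiles; the
#' neighborhood radius decays linearly from `grid_rows / 2` to 1. Gene
#' profiles are centered across spots before training, so portraits read as
#' over/under-expression relative to each gene's mean.
#'
#' @param x an `ExprMatrix`.
#' @param grid_rows,grid_cols grid size (default 55 x 55).
#' @param epochs number of batch epochs.
#' @param seed integer seed for the codebook initialization (random sample of
#'   gene profiles).
#' @param var_keep fraction of genes kept by the variance filter before
#'   training (weakly expressed, low-variance genes form a noise module and
#'   are excluded by default).
#' @return a `SOMModel`: list with `grid_rows`, `grid_cols`, `codebook`
#'   (nodes x spots), `gene_assignment` (named node index per gene),
#'   `node_coords` (nodes x 2), `genes`, `spots`, and a training `log`
#'   (epoch, radius, quantization error).
#' @export
train_som <- function(x, grid_rows = 55L, grid_cols = 55L, epochs = 20L,
                      seed = 1L, var_keep = 0.75) {
  stopifnot(inherits(x, "ExprMatrix"))
  if (grid_rows < 1 || grid_cols < 1) stop("grid must be at least 1x1")
  v <- x$values
  if (nrow(v) == 0L) stop("empty expression matrix")
  if (var_keep < 1) {
    vars <- matrixStats::rowVars(v)
    keep <- vars >= stats::quantile(vars, 1 - var_keep)
    v <- v[keep, , drop = FALSE]
  }
  z <- v - rowMeans(v)
  n_genes <- nrow(z)
  m <- as.integer(grid_rows) * as.integer(grid_cols)
  node_coords <- cbind(row = rep(seq_len(grid_rows), times = grid_cols),
                       col = rep(seq_len(grid_cols), each = grid_rows))
  gd2 <- as.matrix(stats::dist(node_coords))^2

  codebook <- withr::with_seed(as.integer(seed),
    z[sample.int(n_genes, m, replace = n_genes < m), , drop = FALSE])
  rownames(codebook) <- NULL

  radii <- if (epochs > 1) seq(grid_rows / 2, 1, length.out = epochs)
           else max(grid_rows / 2, 1)
  zz <- rowSums(z^2)
  log <- data.frame(epoch = integer(0), radius = numeric(0), qe = numeric(0))
  bmu <- rep(1L, n_genes)
  for (e in seq_len(epochs)) {
    d2 <- outer(zz, rowSums(codebook^2), "+") - 2 * z %*% t(codebook)
    bmu <- max.col(-d2, ties.method = "first")
    qe <- mean(sqrt(pmax(d2[cbind(seq_len(n_genes), bmu)], 0)))
    log <- rbind(log, data.frame(epoch = e, radius = radii[e], qe = qe))
    H <- exp(-gd2 / (2 * radii[e]^2))
    A <- Matrix::sparseMatrix(i = seq_len(n_genes), j = bmu, x = 1,
                              dims = c(n_genes, m))
    Cs <- as.matrix(Matrix::crossprod(A, z))
    ncount <- Matrix::colSums(A)
    num <- H %*% Cs
    den <- as.vector(H %*% ncount)
    upd <- den > 1e-12
    codebook[upd, ] <- num[upd, , drop = FALSE] / den[upd]
  }
  d2 <- outer(zz, rowSums(codebook^2), "+") - 2 * z %*% t(codebook)
  bmu <- max.col(-d2, ties.method = "first")
  names(bmu) <- rownames(z)

  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 codebook = codebook, gene_assignment = bmu,
                 node_coords = node_coords, genes = rownames(z),
                 spots = colnames(z), log = log),
            class = "SOMModel")
}

#' @export
print.SOMModel <- function(x, ...) {
  cat(sprintf("SOMModel: %dx%d grid, %d genes, %d spots, %d epochs\n",
              x$grid_rows, x$grid_cols, length(x$gene_assignment),
              length(x$spots), nrow(x$log)))
  invisible(x)
}

new_portrait <- function(values, subject = NA_character_) {
  structure(values, subject = subject, class = c("Portrait", "matrix"))
}

#' SOM portrait of a single spot
#'
#' The grid-shaped image of one spot's metagene values: portrait value at
#' node n = codebook[n, spot].
#'
#' @param model a `SOMModel`.
#' @param spot a spot id present in the training matrix.
#' @return a `Portrait` (grid_rows x grid_cols matrix).
#' @export
spot_portrait <- function(model, spot) {
  stopifnot(inherits(model, "SOMModel"))
  j <- match(spot, model$spots)
  if (is.na(j)) stop("unknown spot: ", spot)
  new_portrait(matrix(model$codebook[, j], model$grid_rows, model$grid_cols),
               subject = spot)
}

#' Mean portrait over a set of spots
#'
#' Elementwise mean of the member spot portraits (equivalently, the portrait
#' of the codebook row means over those spots).
#'
#' @param model a `SOMModel`.
#' @param spots non-empty vector of spot ids.
#' @param subject optional subject name (e.g. a cluster name).
#' @return a `Portrait`.
#' @export
mean_portrait <- function(model, spots, subject = NA_character_) {
  stopifnot(inherits(model, "SOMModel"))
  if (length(spots) == 0L) stop("empty spot set")
  j <- match(spots, model$spots)
  if (anyNA(j)) stop("unknown spot(s): ", paste(spots[is.na(j)][1]))
  v <- rowMeans(model$codebook[, j, drop = FALSE])
  new_portrait(matrix(v, model$grid_rows, model$grid_cols), subject = subject)
}

#' Difference portrait
#'
#' Elementwise `p1 - p2`; reveals stage-specific program shifts between two
#' mean portraits.
#'
#' @param p1,p2 `Portrait`s on identical grids.
#' @return a `Portrait`.
#' @export
difference_portrait <- function(p1, p2) {
  if (!all(dim(p1) == dim(p2))) stop("portrait shape mismatch")
  new_portrait(unclass(p1) - unclass(p2),
               subject = paste(attr(p1, "subject"), "-", attr(p2, "subject")))
}

# connected components of grid node indices (column-major) under 4- or
# 8-neighborhood adjacency
grid_components <- function(idx, grid_rows, grid_cols, adjacency = 8) {
  if (length(idx) == 0L) return(list())
  member <- logical(grid_rows * grid_cols)
  member[idx] <- TRUE
  offs <- if (adjacency == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  comp <- integer(grid_rows * grid_cols)
  cur <- 0L
  for (start in idx) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      r <- ((k - 1L) %% grid_rows) + 1L
      c <- ((k - 1L) %/% grid_rows) + 1L
      nr <- r + offs[, "dr"]; nc <- c + offs[, "dc"]
      ok <- nr >= 1 & nr <= grid_rows & nc >= 1 & nc <= grid_cols
      nk <- (nc[ok] - 1L) * grid_rows + nr[ok]
      nk <- nk[member[nk] & comp[nk] == 0L]
      comp[nk] <- cur
      queue <- c(queue, nk)
    }
  }
  split(which(comp > 0L), comp[comp > 0L])
}

node_overexpressed <- function(portrait, quantile) {
  v <- unclass(portrait)
  v >= stats::quantile(v, quantile)
}

#' Detect overexpression modules on the SOM grid
#'
#' A node is overexpressed in a portrait when its value reaches that
#' portrait's `overexpression_quantile` quantile; nodes overexpressed in at
#' least `min_support` portraits are candidates, and modules are the
#' connected components of candidate nodes under the chosen adjacency.
#' Modules are labeled `A`, `B`, ... in decreasing member-gene count; a
#' module's support is the set of portraits in which at least half its nodes
#' are overexpressed.
#'
#' @param model a `SOMModel`.
#' @param portraits non-empty (optionally named) list of `Portrait`s.
#' @param overexpression_quantile quantile in (0,1) defining overexpression.
#' @param min_support minimum number of supporting portraits per node.
#' @param adjacency 8 (default; diagonal SOM "mountains") or 4.
#' @return list of `ModuleDef`: each a list with `label`, `node_idx`,
#'   `nodes` (grid coordinates), `genes`, `support`.
#' @export
detect_modules <- function(model, portraits, overexpression_quantile = 0.98,
                           min_support = 3L, adjacency = 8) {
  stopifnot(inherits(model, "SOMModel"))
  if (length(portraits) < 1L) stop("need at least one portrait")
  if (overexpression_quantile <= 0 || overexpression_quantile >= 1)
    stop("overexpression_quantile must be in (0,1)")
  over <- lapply(portraits, node_overexpressed, overexpression_quantile)
  count <- Reduce(`+`, over)
  cand <- which(count >= min_support)
  comps <- grid_components(cand, model$grid_rows, model$grid_cols, adjacency)
  if (length(comps) == 0L) return(list())
  pnames <- names(portraits)
  if (is.null(pnames)) pnames <- as.character(seq_along(portraits))
  mods <- lapply(comps, function(nodes) {
    genes <- names(model$gene_assignment)[model$gene_assignment %in% nodes]
    sup <- pnames[vapply(over, function(o) {
      mean(o[nodes]) >= 0.5
    }, logical(1))]
    list(nodes = model$node_coords[nodes, , drop = FALSE],
         node_idx = nodes, genes = genes, support = sup)
  })
  mods <- mods[order(-vapply(mods, function(m) length(m$genes), 1L))]
  labels <- make.unique(rep(LETTERS, length.out = length(mods)))
  mapply(function(m, l) {
    m$label <- l
    class(m) <- "ModuleDef"
    m
  }, mods, labels, SIMPLIFY = FALSE)
}

#' @export
print.ModuleDef <- function(x, ...) {
  cat(sprintf("Module %s: %d nodes, %d genes, support: %s\n", x$label,
              length(x$node_idx), length(x$genes),
              paste(x$support, collapse = ", ")))
  invisible(x)
}

#' Split a module into signed submodules on a difference portrait
#'
#' Applies the overexpression criterion restricted to the module's nodes,
#' separately on the positive and the negative part of a difference
#' portrait, yielding signed submodules (e.g. the energy-to-lipid
#' sub-modularization a basal-vs-differentiated difference reveals).
#'
#' @param model the `SOMModel` the module came from.
#' @param module a `ModuleDef`.
#' @param difference a difference `Portrait` on the same grid.
#' @param quantile threshold quantile, taken over the positive (resp.
#'   negative) values within the module.
#' @return list of signed `ModuleDef`s, labeled `<parent>+1`, `<parent>-1`, ...;
#'   each carries a `sign` field.
#' @export
submodule_split <- function(model, module, difference, quantile = 0.9) {
  stopifnot(inherits(model, "SOMModel"), inherits(module, "ModuleDef"))
  if (!all(dim(difference) == c(model$grid_rows, model$grid_cols)))
    stop("module/grid mismatch")
  v <- unclass(difference)
  out <- list()
  for (sgn in c(1, -1)) {
    sv <- sgn * v[module$node_idx]
    pos <- sv > 0
    if (!any(pos)) next
    thr <- stats::quantile(sv[pos], quantile)
    cand <- module$node_idx[sv >= thr]
    comps <- grid_components(cand, model$grid_rows, model$grid_cols, 8)
    for (i in seq_along(comps)) {
      nodes <- comps[[i]]
      genes <- names(model$gene_assignment)[model$gene_assignment %in% nodes]
      out[[length(out) + 1L]] <- structure(
        list(label = sprintf("%s%s%d", module$label,
                             if (sgn > 0) "+" else "-", i),
             nodes = model$node_coords[nodes, , drop = FALSE],
             node_idx = nodes, genes = genes, support = module$support,
             sign = sgn),
        class = "ModuleDef")
    }
  }
  out
}

#' Stage-aware module detection along a maturation trajectory
#'
#' Maturation programs activate cumulatively: early genes saturate and stay
#' on in later stages, so a later stage's mean portrait is dominated by
#' earlier programs and a single [detect_modules()] pass merges the stage
#' blocks into one band. This wrapper runs the detection criterion on a
#' battery of portraits that each isolate one program:
#' \itemize{
#'   \item one call per domain mean portrait (first-stage and non-trajectory
#'     programs top their own portrait);
#'   \item for each interior stage, calls on the two flanking increment
#'     portraits (consecutive-stage differences) requiring overexpression in
#'     both — only genes still rising across both transitions qualify —
#'     scanned over a small quantile ladder;
#'   \item for the terminal stage, a call on the trajectory-curvature
#'     portrait (last increment minus twice the previous increment), which
#'     cancels both saturated and steadily rising programs.
#' }
#'
#' @param model a `SOMModel`.
#' @param labels named character vector of per-spot domain labels; names are
#'   spot ids known to the model.
#' @param stages ordered character vector (earliest first) of the trajectory
#'   stage labels; each must appear in `labels`. Non-stage labels are treated
#'   as standalone domains.
#' @param overexpression_quantile quantile for the domain and curvature
#'   calls.
#' @param transit_quantiles quantile ladder for the interior-stage calls.
#' @return flat list of `ModuleDef`s; each carries a `source` field naming
#'   the portrait battery entry it came from, and labels are prefixed with
#'   that source so they are unique across calls.
#' @export
detect_stage_modules <- function(model, labels, stages,
                                 overexpression_quantile = 0.9,
                                 transit_quantiles = c(0.85, 0.88, 0.9)) {
  stopifnot(inherits(model, "SOMModel"))
  if (is.null(names(labels))) stop("labels must be named by spot id")
  doms <- sort(unique(as.character(labels)))
  if (!all(stages %in% doms)) stop("stage without labeled spots")
  ports <- lapply(doms, function(dm)
    mean_portrait(model, names(labels)[labels == dm], subject = dm))
  names(ports) <- doms

  tag <- function(mods, src) lapply(mods, function(m) {
    m$source <- src
    m$label <- paste0(src, ":", m$label)
    m
  })
  out <- list()
  for (dm in doms)
    out <- c(out, tag(detect_modules(model, ports[dm],
                                     overexpression_quantile, 1L),
                      paste0("domain_", dm)))
  k <- length(stages)
  if (k >= 3L) {
    dps <- lapply(seq_len(k - 1L), function(i)
      difference_portrait(ports[[stages[i + 1L]]], ports[[stages[i]]]))
    for (i in seq(2L, k - 1L))
      for (q in transit_quantiles)
        out <- c(out, tag(detect_modules(model, dps[c(i - 1L, i)], q, 2L),
                          sprintf("transit_%s_q%g", stages[i], q)))
    curv <- difference_portrait(
      difference_portrait(dps[[k - 1L]], dps[[k - 2L]]), dps[[k - 2L]])
    out <- c(out, tag(detect_modules(model, list(curv),
                                     overexpression_quantile, 1L),
                      paste0("terminal_", stages[k])))
  }
  out
}

#' Per-spot expression score of a module
#'
#' Mean normalized expression of the module's member genes per spot, emitted
#' with lattice positions for tissue coloring.
#'
#' @param ds the [spot_dataset()] providing positions.
#' @param x an `ExprMatrix`.
#' @param module a `ModuleDef`.
#' @return data frame: `spot_id`, `array_row`, `array_col`, `score`.
#' @export
module_expression <- function(ds, x, module) {
  stopifnot(inherits(ds, "SpotDataset"), inherits(x, "ExprMatrix"))
  genes <- intersect(module$genes, rownames(x$values))
  if (length(genes) == 0L) stop("no module gene present in the matrix")
  score <- colMeans(x$values[genes, , drop = FALSE])
  pos <- ds$positions[match(colnames(x$values), ds$positions$spot_id), ]
  data.frame(spot_id = colnames(x$values),
             array_row = pos$array_row, array_col = pos$array_col,
             score = unname(score))
}

#' Module co-appearance map
#'
#' Entry (i, j) is the fraction of portraits in which modules i and j are
#' both overexpressed (a module counts as overexpressed in a portrait when at
#' least half its nodes pass the quantile criterion). The diagonal holds each
#' module's overexpression frequency.
#'
#' @param portraits list of `Portrait`s.
#' @param modules non-empty list of `ModuleDef`s.
#' @param overexpression_quantile quantile in (0,1).
#' @return symmetric modules x modules matrix.
#' @export
co_appearance_map <- function(portraits, modules,
                              overexpression_quantile = 0.98) {
  if (length(modules) == 0L) stop("empty module list")
  over <- vapply(portraits, function(p) {
    o <- node_overexpressed(p, overexpression_quantile)
    vapply(modules, function(m) mean(o[m$node_idx]) >= 0.5, logical(1))
  }, logical(length(modules)))
  over <- matrix(over, nrow = length(modules))  # modules x portraits
  co <- tcrossprod(over * 1) / length(portraits)
  labs <- vapply(modules, `[[`, "", "label")
  dimnames(co) <- list(labs, labs)
  co
}

#' Plot a portrait as a diverging heatmap
#'
#' Blue-white-red, symmetric about zero (red = overexpressed metagenes).
#'
#' @param x a `Portrait`.
#' @param ... passed to [graphics::image()].
#' @export
plot.Portrait <- function(x, ...) {
  v <- unclass(x)
  lim <- max(abs(v), 1e-12)
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  graphics::image(t(v[nrow(v):1, , drop = FALSE]), zlim = c(-lim, lim),
                  col = pal, axes = FALSE,
                  main = attr(x, "subject"), ...)
  invisible(x)
}
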