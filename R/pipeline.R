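#' Default pipeline configuration
#'
#' One flat list of every tunable the pipeline uses; all randomized stages
#' derive their seeds from the single `seed` entry. Any entry can be
#' overridden via a key-value config file ([read_config()]) or by argument.
#'
#' @param ... overrides as named arguments.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    lattice_rows = 40, lattice_cols = 40, n_genes = 2000,
    library_size = 5000, dispersion = 0.3,
    min_counts = 500, min_genes = 200, scale_total = 1e4,
    n_components = 30, k_neighbors = 20, resolution = 0.8,
    som_rows = 20, som_cols = 20, som_epochs = 20, var_keep = 0.75,
    overexpression_quantile = 0.90, min_support = 1,
    n_centroids = 25, n_top = 500, n_bins = 20, window_size = 50,
    shared_fraction = 0.5, stage_shift = 1,
    logfc_threshold = 0.1, sig_cutoff = 0.05)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis pipeline on synthetic sections
#'
#' Simulate a gland section (plus a second gland sharing part of its
#' maturation program), preprocess, cluster and call markers, train the SOM
#' and detect modules, fit pseudotime with GS windows, compare the two
#' glands' pseudotime gene lists (Venn, stage Sankey, cross-gland DEGs,
#' integrated embedding), and run overrepresentation analysis — writing every
#' table under `outdir` together with a manifest. Two runs with equal config
#' produce byte-identical outputs.
#'
#' @param outdir output directory.
#' @param config from [default_config()] or [read_config()].
#' @param stage run only up to this stage (`"simulate"`, `"preprocess"`,
#'   `"cluster"`, `"markers"`, `"som"`, `"pseudotime"`, `"compare"`,
#'   `"enrich"` or `"all"`), writing the tables available at that point;
#'   `"simulate"` additionally writes the two sections as on-disk bundles.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(outdir, config = default_config(), stage = "all") {
  ladder <- c("simulate", "preprocess", "cluster", "markers", "som",
              "pseudotime", "compare", "enrich", "all")
  stage <- match.arg(stage, ladder)
  upto <- if (stage == "all") length(ladder) else match(stage, ladder)
  want <- function(s) upto >= match(s, ladder)
  cfg <- default_config()
  cfg[names(config)] <- config
  seed <- as.integer(cfg$seed)
  out <- list(config = cfg)
  files <- list()

  specA <- gland_spec(lattice_rows = cfg$lattice_rows,
                      lattice_cols = cfg$lattice_cols,
                      n_genes = cfg$n_genes,
                      library_size = cfg$library_size,
                      dispersion = cfg$dispersion, seed = seed)
  specB <- gland_spec(lattice_rows = cfg$lattice_rows,
                      lattice_cols = cfg$lattice_cols,
                      n_genes = cfg$n_genes,
                      library_size = cfg$library_size,
                      dispersion = cfg$dispersion,
                      stage_names = c("SEB-B", "SEB-1", "SEB-2"),
                      seed = seed + 1000L)
  exp2 <- generate_two_gland_experiment(specA, specB,
                                        shared_fraction = cfg$shared_fraction,
                                        stage_shift = cfg$stage_shift,
                                        seed = seed + 2000L)
  dsA <- exp2$datasetA
  dsB <- exp2$datasetB
  out$datasetA <- dsA
  out$datasetB <- dsB
  out$truth <- exp2$truth
  files$gene_truth <- exp2$truth$genes
  if (stage == "simulate") {
    write_visium_bundle(dsA, file.path(outdir, "sectionA"))
    write_visium_bundle(dsB, file.path(outdir, "sectionB"))
  }

  fA <- NULL
  if (want("preprocess")) {
    fA <- filter_spots(dsA, cfg$min_counts, cfg$min_genes)
    xA <- normalize_log(fA, cfg$scale_total)
    pcs <- pca_embed(xA, cfg$n_components)
    tot <- Matrix::colSums(dsA$counts)
    ngn <- Matrix::colSums(dsA$counts > 0)
    files$spot_qc <- data.frame(spot_id = dsA$spot_ids,
                                total_counts = as.integer(tot),
                                n_genes = as.integer(ngn),
                                kept = dsA$spot_ids %in% fA$spot_ids)
  }

  if (want("cluster")) {
    clusters <- snn_cluster(pcs, cfg$k_neighbors, cfg$resolution, seed)
    umap <- embed_2d(pcs, seed = seed)
    out$clusters <- clusters
    out$umap <- umap
    files$clusters <- data.frame(spot_id = names(clusters),
                                 label = unname(clusters))
    files$umap <- data.frame(spot_id = rownames(umap), UMAP1 = umap[, 1],
                             UMAP2 = umap[, 2])
  }

  if (want("markers")) {
    # markers of the largest cluster vs the rest (per-cluster tables are the
    # analysis scripts' job; the pipeline exercises one deterministic call)
    lab <- stats::setNames(as.character(clusters), names(clusters))
    others <- setdiff(unique(lab), "1")
    markers <- wilcoxon_markers(xA, lab, "1", others, cfg$logfc_threshold)
    out$markers <- markers
    files$markers_cluster1 <- markers
  }

  stagesA <- specA$stage_names
  if (want("som")) {
    som <- train_som(xA, cfg$som_rows, cfg$som_cols, cfg$som_epochs, seed,
                     cfg$var_keep)
    domA <- fA$labels
    dom_portraits <- lapply(sort(unique(domA)), function(dm)
      mean_portrait(som, names(domA)[domA == dm], subject = dm))
    names(dom_portraits) <- sort(unique(domA))
    modules <- detect_modules(som, dom_portraits,
                              cfg$overexpression_quantile, cfg$min_support)
    stage_modules <- detect_stage_modules(som, domA, stagesA,
                                          cfg$overexpression_quantile)
    diffs <- list()
    for (i in seq_len(length(stagesA) - 1)) {
      nmm <- paste0(stagesA[i + 1], "_vs_", stagesA[i])
      diffs[[nmm]] <- difference_portrait(dom_portraits[[stagesA[i + 1]]],
                                          dom_portraits[[stagesA[i]]])
    }
    coapp <- if (length(modules) >= 2)
      co_appearance_map(dom_portraits, modules, cfg$overexpression_quantile)
    else matrix(numeric(0), 0, 0)
    out$som <- som
    out$modules <- modules
    out$stage_modules <- stage_modules
    out$portraits <- dom_portraits
    files$modules <- data.frame(
      label = vapply(modules, `[[`, "", "label"),
      n_nodes = vapply(modules, function(m) length(m$node_idx), 1L),
      n_genes = vapply(modules, function(m) length(m$genes), 1L),
      genes = vapply(modules, function(m) paste(m$genes, collapse = ","), ""),
      support = vapply(modules, function(m)
        paste(m$support, collapse = ","), ""))
    files$stage_modules <- data.frame(
      label = vapply(stage_modules, `[[`, "", "label"),
      source = vapply(stage_modules, `[[`, "", "source"),
      n_nodes = vapply(stage_modules, function(m) length(m$node_idx), 1L),
      n_genes = vapply(stage_modules, function(m) length(m$genes), 1L),
      genes = vapply(stage_modules, function(m)
        paste(m$genes, collapse = ","), ""))
    files$co_appearance <- coapp
    for (nmm in names(dom_portraits))
      files[[paste0("portrait_", gsub("[^A-Za-z0-9]", "_", nmm))]] <-
        dom_portraits[[nmm]]
    for (nmm in names(diffs))
      files[[paste0("difference_", gsub("[^A-Za-z0-9]", "_", nmm))]] <-
        diffs[[nmm]]
  }

  if (want("pseudotime")) {
    gsp <- names(domA)[domA %in% stagesA]
    umap_g <- umap[gsp, , drop = FALSE]
    bb <- fit_principal_graph(umap_g, cfg$n_centroids, seed)
    ptres <- assign_pseudotime(bb, umap_g,
                               names(domA)[domA == stagesA[1]])
    xg <- structure(list(values = xA$values[, gsp, drop = FALSE],
                         scale_total = xA$scale_total, pseudocount = 1),
                    class = "ExprMatrix")
    ptA <- order_and_window(pt_degs(xg, ptres$pt, cfg$n_top, cfg$n_bins),
                            cfg$window_size, model = som)
    out$pseudotime <- ptres
    out$pt_genes <- ptA
    files$pseudotime <- data.frame(spot_id = names(ptres$pt),
                                   pt = unname(ptres$pt), edge = ptres$edge)
    files$pt_genes <- as.data.frame(ptA)
    files$window_profiles <- attr(ptA, "window_profiles")
  }

  if (want("compare")) {
    fB <- filter_spots(dsB, cfg$min_counts, cfg$min_genes)
    xB <- normalize_log(fB, cfg$scale_total)
    domB <- fB$labels
    stagesB <- specB$stage_names
    gspB <- names(domB)[domB %in% stagesB]
    umapB <- embed_2d(pca_embed(xB, cfg$n_components), seed = seed + 1L)
    bbB <- fit_principal_graph(umapB[gspB, , drop = FALSE], cfg$n_centroids,
                               seed + 1L)
    ptresB <- assign_pseudotime(bbB, umapB[gspB, , drop = FALSE],
                                names(domB)[domB == stagesB[1]])
    xgB <- structure(list(values = xB$values[, gspB, drop = FALSE],
                          scale_total = xB$scale_total, pseudocount = 1),
                     class = "ExprMatrix")
    ptB <- order_and_window(pt_degs(xgB, ptresB$pt, cfg$n_top, cfg$n_bins),
                            cfg$window_size)

    venn <- venn_lists(ptA$gene, ptB$gene)
    shared_present <- intersect(intersect(venn$shared, rownames(xA$values)),
                                rownames(xB$values))
    stA <- assign_stage(shared_present, xA, domA, stagesA)
    stB <- assign_stage(shared_present, xB, domB, stagesB)
    sankey <- sankey_counts(shared_present, stA, stB)

    # cross-gland DEGs on the shared-gene joint matrix: secretory cells of A
    # (basal + differentiated pooled) vs those of B
    shared_genes <- intersect(rownames(xA$values), rownames(xB$values))
    joint <- cbind(xA$values[shared_genes, gsp, drop = FALSE],
                   xB$values[shared_genes, gspB, drop = FALSE])
    colnames(joint) <- c(paste0("A_", gsp), paste0("B_", gspB))
    xj <- structure(list(values = joint, scale_total = cfg$scale_total,
                         pseudocount = 1), class = "ExprMatrix")
    labj <- stats::setNames(c(paste0("A_", domA[gsp]),
                              paste0("B_", domB[gspB])),
                            colnames(joint))
    cg <- cross_gland_degs(xj, labj,
                           paste0("A_", stagesA[1:2]),
                           paste0("B_", stagesB[1:2]),
                           cfg$logfc_threshold, cfg$sig_cutoff)
    integrated <- integrate_datasets(fA, fB, cfg$n_components, seed)
    out$venn <- venn
    out$sankey <- sankey
    out$cross_gland <- cg
    out$integrated <- integrated
    files$venn <- data.frame(part = c("shared", "uniqueA", "uniqueB"),
                             n = c(length(venn$shared), length(venn$uniqueA),
                                   length(venn$uniqueB)))
    files$sankey <- sankey$counts
    files$stage_assignments <- data.frame(
      gene = names(stA),
      stage_A = as.character(stA),
      stage_B = as.character(stB[names(stA)]))
    files$cross_gland_volcano <- cg$volcano
    files$integrated_umap <- integrated
  }

  if (want("enrich")) {
    prog_sets <- split(specA$programs$gene, specA$programs$stage)
    top_pt <- ptA$gene[order(ptA$rank)][seq_len(min(100, nrow(ptA)))]
    enr <- ora(top_pt, universe = rownames(xA$values), gene_sets = prog_sets)
    coloring <- functional_coloring(fA, xA, prog_sets[[stagesA[2]]],
                                    coords = umap)
    out$enrichment <- enr
    files$enrichment <- enr
    files$functional_coloring <- coloring
  }

  do.call(write_results, c(list(outdir = outdir), files, list(config = cfg)))
  invisible(out)
}
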