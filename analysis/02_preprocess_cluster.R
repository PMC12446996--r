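#!/usr/bin/env Rscript
# Quality-filter section A, log-normalize, embed (PCA + UMAP), cluster the
# spots by shared-nearest-neighbor modularity and call per-cluster markers.
source(file.path("analysis", "common.R"))

seed <- as.integer(cfg$seed)
dsA <- read_visium_bundle(file.path(data_dir, "sectionA"))
labels_file <- file.path(data_dir, "sectionA", "labels.tsv")
planted <- utils::read.delim(labels_file)
dsA$labels <- stats::setNames(planted$label, planted$spot_id)[dsA$spot_ids]

fA <- filter_spots(dsA, cfg$min_counts, cfg$min_genes)
xA <- normalize_log(fA, cfg$scale_total)
pcs <- pca_embed(xA, cfg$n_components)
umap <- embed_2d(pcs, seed = seed)
clusters <- snn_cluster(pcs, cfg$k_neighbors, cfg$resolution, seed)

lab <- stats::setNames(as.character(clusters), names(clusters))
marker_tables <- lapply(sort(unique(lab)), function(cl)
  cbind(cluster = cl,
        wilcoxon_markers(xA, lab, cl, setdiff(unique(lab), cl),
                         cfg$logfc_threshold)))
markers <- do.call(rbind, marker_tables)

tot <- Matrix::colSums(dsA$counts)
ngn <- Matrix::colSums(dsA$counts > 0)
cache_put("fA", fA)
cache_put("xA", xA)
cache_put("pcs", pcs)
cache_put("umap", umap)
cache_put("clusters", clusters)
write_results(results_dir,
              spot_qc = data.frame(spot_id = dsA$spot_ids,
                                   total_counts = as.integer(tot),
                                   n_genes = as.integer(ngn),
                                   kept = dsA$spot_ids %in% fA$spot_ids),
              clusters = data.frame(spot_id = names(clusters),
                                    label = unname(clusters)),
              umap = data.frame(spot_id = rownames(umap),
                                UMAP1 = umap[, 1], UMAP2 = umap[, 2]),
              markers = markers,
              config = cfg)
message("clustered ", length(clusters), " spots into ",
        length(unique(clusters)), " clusters")
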