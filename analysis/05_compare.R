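#!/usr/bin/env Rscript
# Compare the two glands: pseudotime gene lists (Venn), per-gene maturation
# stage assignment and the stage-flow Sankey table, cross-gland differential
# expression, and a joint embedding over the shared genes.
source(file.path("analysis", "common.R"))

seed <- as.integer(cfg$seed)
specA <- cache_get("specA")
specB <- cache_get("specB")
fA <- cache_get("fA")
xA <- cache_get("xA")
ptA <- cache_get("ptA")
stagesA <- specA$stage_names
stagesB <- specB$stage_names

dsB <- read_visium_bundle(file.path(data_dir, "sectionB"))
labels_file <- file.path(data_dir, "sectionB", "labels.tsv")
planted <- utils::read.delim(labels_file)
dsB$labels <- stats::setNames(planted$label, planted$spot_id)[dsB$spot_ids]
fB <- filter_spots(dsB, cfg$min_counts, cfg$min_genes)
xB <- normalize_log(fB, cfg$scale_total)
domA <- fA$labels
domB <- fB$labels

# gland B trajectory and pseudotime gene list
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
shared <- intersect(intersect(venn$shared, rownames(xA$values)),
                    rownames(xB$values))
stA <- assign_stage(shared, xA, domA, stagesA)
stB <- assign_stage(shared, xB, domB, stagesB)
sankey <- sankey_counts(shared, stA, stB)

gsp <- names(domA)[domA %in% stagesA]
shared_genes <- intersect(rownames(xA$values), rownames(xB$values))
joint <- cbind(xA$values[shared_genes, gsp, drop = FALSE],
               xB$values[shared_genes, gspB, drop = FALSE])
colnames(joint) <- c(paste0("A_", gsp), paste0("B_", gspB))
xj <- structure(list(values = joint, scale_total = cfg$scale_total,
                     pseudocount = 1), class = "ExprMatrix")
labj <- stats::setNames(c(paste0("A_", domA[gsp]), paste0("B_", domB[gspB])),
                        colnames(joint))
cg <- cross_gland_degs(xj, labj, paste0("A_", stagesA[1:2]),
                       paste0("B_", stagesB[1:2]),
                       cfg$logfc_threshold, cfg$sig_cutoff)
integrated <- integrate_datasets(fA, fB, cfg$n_components, seed)

write_results(results_dir,
              venn = data.frame(part = c("shared", "uniqueA", "uniqueB"),
                                n = c(length(venn$shared),
                                      length(venn$uniqueA),
                                      length(venn$uniqueB))),
              sankey = sankey$counts,
              stage_assignments = data.frame(
                gene = names(stA),
                stage_A = as.character(stA),
                stage_B = as.character(stB[names(stA)])),
              cross_gland_volcano = cg$volcano,
              integrated_umap = integrated,
              config = cfg)
message(length(venn$shared), " shared pseudotime genes; Sankey total ",
        sankey$total)
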