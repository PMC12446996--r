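#!/usr/bin/env Rscript
# Fit the maturation trajectory: principal graph over the gland spots'
# embedding, pseudotime from the basal stage, pseudotime-associated genes and
# the consecutive GS windows with their mean profiles and grid portraits.
source(file.path("analysis", "common.R"))

seed <- as.integer(cfg$seed)
specA <- cache_get("specA")
fA <- cache_get("fA")
xA <- cache_get("xA")
umap <- cache_get("umap")
som <- cache_get("som")
stages <- specA$stage_names

domA <- fA$labels
gsp <- names(domA)[domA %in% stages]
umg <- umap[gsp, , drop = FALSE]
bb <- fit_principal_graph(umg, cfg$n_centroids, seed)
ptres <- assign_pseudotime(bb, umg, names(domA)[domA == stages[1]])

xg <- structure(list(values = xA$values[, gsp, drop = FALSE],
                     scale_total = xA$scale_total, pseudocount = 1),
                class = "ExprMatrix")
ptA <- order_and_window(pt_degs(xg, ptres$pt, cfg$n_top, cfg$n_bins),
                        cfg$window_size, model = som)

cache_put("ptres", ptres)
cache_put("ptA", ptA)
write_results(results_dir,
              backbone_edges = ptres$backbone$edges,
              pseudotime = data.frame(spot_id = names(ptres$pt),
                                      pt = unname(ptres$pt),
                                      edge = ptres$edge,
                                      offset = ptres$offset),
              pt_genes = as.data.frame(ptA),
              window_profiles = attr(ptA, "window_profiles"),
              config = cfg)
message("pseudotime over ", length(ptres$pt), " gland spots; ",
        length(unique(ptA$window)), " windows")
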