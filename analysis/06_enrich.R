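#!/usr/bin/env Rscript
# Overrepresentation analysis of the top pseudotime genes against the
# planted program gene sets (stored and re-read as a GMT collection), plus
# functional coloring of the tissue map by one program set.
source(file.path("analysis", "common.R"))

specA <- cache_get("specA")
fA <- cache_get("fA")
xA <- cache_get("xA")
umap <- cache_get("umap")
ptA <- cache_get("ptA")
stages <- specA$stage_names

# program gene sets as a GMT round-trip (the collection file other studies
# would supply)
prog_sets <- split(specA$programs$gene, specA$programs$stage)
gmt_path <- file.path(data_dir, "programs.gmt")
writeLines(vapply(names(prog_sets), function(nm)
  paste(c(nm, "planted maturation program", prog_sets[[nm]]),
        collapse = "\t"), ""), gmt_path)
sets <- read_gmt(gmt_path)

top_pt <- ptA$gene[order(ptA$rank)][seq_len(min(100, nrow(ptA)))]
enr <- ora(top_pt, universe = rownames(xA$values), gene_sets = sets)
coloring <- functional_coloring(fA, xA, sets[[stages[2]]], coords = umap)

write_results(results_dir,
              enrichment = enr,
              functional_coloring = coloring,
              config = cfg)
message("top enriched set: ", enr$set[1], " (q = ",
        signif(enr$q[1], 3), ")")
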