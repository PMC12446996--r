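#!/usr/bin/env Rscript
# Train the gene-space self-organizing map, render per-domain mean portraits
# and stage difference portraits, and detect transcriptional modules — both
# the plain overexpression modules and the stage-aware battery that resolves
# cumulatively activated maturation programs.
source(file.path("analysis", "common.R"))

seed <- as.integer(cfg$seed)
specA <- cache_get("specA")
fA <- cache_get("fA")
xA <- cache_get("xA")
stages <- specA$stage_names

som <- train_som(xA, cfg$som_rows, cfg$som_cols, cfg$som_epochs, seed,
                 cfg$var_keep)
domA <- fA$labels
doms <- sort(unique(domA))
portraits <- lapply(doms, function(dm)
  mean_portrait(som, names(domA)[domA == dm], subject = dm))
names(portraits) <- doms

modules <- detect_modules(som, portraits, cfg$overexpression_quantile,
                          cfg$min_support)
stage_modules <- detect_stage_modules(som, domA, stages,
                                      cfg$overexpression_quantile)
diffs <- list()
for (i in seq_len(length(stages) - 1)) {
  nm <- paste0(stages[i + 1], "_vs_", stages[i])
  diffs[[nm]] <- difference_portrait(portraits[[stages[i + 1]]],
                                     portraits[[stages[i]]])
}
submods <- list()
if (length(modules) && length(diffs))
  submods <- submodule_split(som, modules[[1]], diffs[[1]])
coapp <- matrix(numeric(0), 0, 0)
if (length(modules) >= 2)
  coapp <- co_appearance_map(portraits, modules, cfg$overexpression_quantile)

module_table <- function(mods) data.frame(
  label = vapply(mods, `[[`, "", "label"),
  n_nodes = vapply(mods, function(m) length(m$node_idx), 1L),
  n_genes = vapply(mods, function(m) length(m$genes), 1L),
  genes = vapply(mods, function(m) paste(m$genes, collapse = ","), ""))

cache_put("som", som)
cache_put("portraits", portraits)
cache_put("stage_modules", stage_modules)
out <- list(modules = module_table(modules),
            stage_modules = cbind(
              module_table(stage_modules),
              source = vapply(stage_modules, `[[`, "", "source")),
            submodules = module_table(submods),
            co_appearance = coapp)
for (nm in names(portraits))
  out[[paste0("portrait_", gsub("[^A-Za-z0-9]", "_", nm))]] <- portraits[[nm]]
for (nm in names(diffs))
  out[[paste0("difference_", gsub("[^A-Za-z0-9]", "_", nm))]] <- diffs[[nm]]
do.call(write_results, c(list(outdir = results_dir), out,
                         list(config = cfg)))
message(length(modules), " joint modules, ", length(stage_modules),
        " stage-aware modules")
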