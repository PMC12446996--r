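#!/usr/bin/env Rscript
# Simulate the two synthetic gland sections (the study section A and a
# second gland B sharing half its maturation program one stage later) and
# write them as on-disk bundles plus the planted truth tables.
source(file.path("analysis", "common.R"))

seed <- as.integer(cfg$seed)
specA <- gland_spec(lattice_rows = cfg$lattice_rows,
                    lattice_cols = cfg$lattice_cols,
                    n_genes = cfg$n_genes, library_size = cfg$library_size,
                    dispersion = cfg$dispersion, seed = seed)
specB <- gland_spec(lattice_rows = cfg$lattice_rows,
                    lattice_cols = cfg$lattice_cols,
                    n_genes = cfg$n_genes, library_size = cfg$library_size,
                    dispersion = cfg$dispersion,
                    stage_names = c("SEB-B", "SEB-1", "SEB-2"),
                    seed = seed + 1000L)
exp2 <- generate_two_gland_experiment(specA, specB,
                                      shared_fraction = cfg$shared_fraction,
                                      stage_shift = cfg$stage_shift,
                                      seed = seed + 2000L)

write_visium_bundle(exp2$datasetA, file.path(data_dir, "sectionA"))
write_visium_bundle(exp2$datasetB, file.path(data_dir, "sectionB"))
cache_put("specA", specA)
cache_put("specB", specB)
cache_put("exp2_truth", exp2$truth)
write_results(results_dir,
              gene_truth = exp2$truth$genes,
              spot_truth_A = exp2$truth$A$spots,
              config = cfg)
message("simulated sections written to ", data_dir)
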