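# Shared setup for the numbered analysis drivers: configuration, output
# locations and a small cache for intermediate objects passed between steps.
suppressPackageStartupMessages(library(glandst))

results_dir <- file.path("results")
cache_dir <- file.path(results_dir, "cache")
data_dir <- file.path(results_dir, "data")
for (d in c(results_dir, cache_dir, data_dir))
  dir.create(d, showWarnings = FALSE, recursive = TRUE)

config_path <- file.path("analysis", "config.txt")
cfg <- if (file.exists(config_path)) {
  over <- read_config(config_path)
  do.call(default_config, over)
} else {
  default_config()
}

cache_put <- function(name, value)
  saveRDS(value, file.path(cache_dir, paste0(name, ".rds")))
cache_get <- function(name) {
  path <- file.path(cache_dir, paste0(name, ".rds"))
  if (!file.exists(path))
    stop("missing intermediate '", name, "': run the earlier drivers first")
  readRDS(path)
}
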