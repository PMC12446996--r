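# Shared small fixtures, all generated in code.

# A tiny deterministic SpotDataset: `g` genes x `s` spots with integer counts.
toy_dataset <- function(g = 6L, s = 4L, seed = 42L, labels = NULL) {
  counts <- withr::with_seed(seed, matrix(rpois(g * s, 5), g, s))
  spot_ids <- paste0("S", seq_len(s))
  pos <- data.frame(spot_id = spot_ids, in_tissue = 1L,
                    array_row = rep(seq_len(ceiling(s / 2)), length.out = s),
                    array_col = rep(1:2, length.out = s),
                    pxl_row = seq_len(s), pxl_col = seq_len(s))
  spot_dataset(counts, paste0("g", seq_len(g)), spot_ids, positions = pos,
               labels = labels)
}

# ExprMatrix from an explicit value matrix.
toy_expr <- function(values) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  structure(list(values = values, scale_total = 1e4, pseudocount = 1),
            class = "ExprMatrix")
}

# Expression with two gene blocks, each overexpressed in half the spots:
# yields a SOM with two well-separated populated regions.
toy_som_input <- function(n_genes = 60L, n_spots = 20L, seed = 1L) {
  withr::with_seed(seed, {
    base <- matrix(rnorm(n_genes * n_spots, 0, 0.1), n_genes, n_spots)
    half_g <- n_genes %/% 2
    half_s <- n_spots %/% 2
    base[seq_len(half_g), seq_len(half_s)] <-
      base[seq_len(half_g), seq_len(half_s)] + 2
    base[(half_g + 1):n_genes, (half_s + 1):n_spots] <-
      base[(half_g + 1):n_genes, (half_s + 1):n_spots] + 2
    toy_expr(base)
  })
}

# The default synthetic section plus its preprocessing products, computed
# once per test run (acceptance-scale shared fixture).
section_fixture <- local({
  cache <- NULL
  function(seed = 1L) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    spec <- gland_spec(seed = seed)
    sec <- generate_gland_section(spec, keep_intensity = TRUE)
    f <- suppressMessages(filter_spots(sec$dataset, 500, 200))
    x <- normalize_log(f)
    cache <<- list(seed = seed, spec = spec, section = sec, filtered = f,
                   expr = x)
    cache
  }
})

# Hand-built SOMModel on a small grid with a fixed gene assignment, for
# exercising the module-detection geometry without training.
fake_som <- function(grid_rows, grid_cols, assignment, n_spots = 1L,
                     codebook = NULL) {
  if (is.null(codebook))
    codebook <- matrix(0, grid_rows * grid_cols, n_spots)
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    codebook = codebook,
    gene_assignment = assignment,
    node_coords = cbind(row = rep(seq_len(grid_rows), times = grid_cols),
                        col = rep(seq_len(grid_cols), each = grid_rows)),
    genes = names(assignment), spots = paste0("S", seq_len(n_spots)),
    log = data.frame()), class = "SOMModel")
}

# Portrait on a small grid from an explicit matrix.
fake_portrait <- function(values) glandst:::new_portrait(values)

# Best-match F1 of a planted gene set against a list of detected modules.
f1_best <- function(planted, modules) {
  if (length(modules) == 0L) return(0)
  max(vapply(modules, function(m) {
    hit <- length(intersect(m$genes, planted))
    2 * hit / (length(m$genes) + length(planted))
  }, numeric(1)))
}

# Adjusted Rand index between two labelings (Hubert & Arabie).
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sn <- choose(sum(tab), 2)
  expected <- si * sj / sn
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# group assignments (oracle for wilcoxon_markers).
exact_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2, function(idx)
    sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * length(b) / 2
  min(1, mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# Exact hypergeometric upper tail by enumeration over all C(N, n) draws
# (oracle for ora), computed with exact rational arithmetic via choose().
exact_ora_p <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
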