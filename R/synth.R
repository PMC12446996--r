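#' Specification of a synthetic gland section
#'
#' Describes a Visium-like capture lattice containing one or more gland acini
#' with concentric maturation layers (basal cells at the acinus rim, a duct at
#' its center) plus non-gland tissue domains. Radial depth `d` runs from 0 at
#' the rim to 1 at the center; `stage_breaks` split `d` into ordered
#' maturation stages. Each maturation gene carries an activation midpoint
#' along `d` and a log-scale amplitude; its activation is a smooth sigmoid in
#' `d` centered at that midpoint. Counts are negative-binomial around
#' `library_size` times the softmax-normalized per-spot gene intensities.
#'
#' @param lattice_rows,lattice_cols spot-grid size.
#' @param acini data frame with columns `row`, `col`, `radius` (lattice
#'   units), one disc per acinus.
#' @param stage_breaks increasing numbers in (0,1); `k` breaks define `k + 1`
#'   stages of radial depth.
#' @param stage_names one name per stage (default `MEI-B`, `MEI-DIFF`,
#'   `MEI-DUCT` for 3 stages, else `S1..Sk`).
#' @param duct_radius_fraction optional; when supplied it overrides the last
#'   stage break as `1 - duct_radius_fraction`, i.e. the central duct occupies
#'   the disc of this radius fraction.
#' @param programs data frame of maturation genes: columns `gene`, `stage`,
#'   `amplitude`, `midpoint` (activation midpoint in depth units).
#' @param background_domains data frame of non-gland domain genes: columns
#'   `gene`, `domain`, `amplitude`. Non-gland spots are split into vertical
#'   bands, one per domain, in the order the domains first appear.
#' @param n_genes total gene-universe size; ids `G0001...`.
#' @param cells_per_spot integer range of cells mixed per spot.
#' @param library_size expected total counts per spot.
#' @param dispersion negative-binomial overdispersion (variance =
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param baseline_sd standard deviation of per-gene baseline log-intensity.
#' @param sigmoid_tau steepness scale of the activation sigmoid (depth units).
#' @param depth_jitter_sd within-spot cell depth jitter (depth units),
#'   emulating the mixing of several cells per 55 um spot.
#' @param seed integer RNG seed.
#'
#' @return an object of class `GlandSpec`.
#' @export
gland_spec <- function(lattice_rows = 40L, lattice_cols = 40L,
                       acini = NULL,
                       stage_breaks = c(1 / 3, 2 / 3),
                       stage_names = NULL,
                       duct_radius_fraction = NULL,
                       programs = NULL,
                       background_domains = NULL,
                       n_genes = 2000L,
                       cells_per_spot = c(7L, 12L),
                       library_size = 5000,
                       dispersion = 0.3,
                       baseline_sd = 0.5,
                       sigmoid_tau = 0.08,
                       depth_jitter_sd = 0.06,
                       seed = 1L) {
  if (!is.null(duct_radius_fraction)) {
    if (duct_radius_fraction <= 0 || duct_radius_fraction >= 1)
      stop("duct_radius_fraction must be in (0,1)")
    stage_breaks[length(stage_breaks)] <- 1 - duct_radius_fraction
  }
  if (is.unsorted(stage_breaks, strictly = TRUE) ||
      any(stage_breaks <= 0) || any(stage_breaks >= 1))
    stop("stage_breaks must be strictly increasing within (0,1)")
  n_stages <- length(stage_breaks) + 1L
  if (is.null(stage_names)) {
    stage_names <- if (n_stages == 3L) c("MEI-B", "MEI-DIFF", "MEI-DUCT")
    else paste0("S", seq_len(n_stages))
  }
  if (length(stage_names) != n_stages) stop("need one name per stage")
  if (is.null(acini))
    acini <- data.frame(row = c(10, 10, 29, 29), col = c(10, 29, 10, 29),
                        radius = 7)
  if (any(acini$radius <= 0)) stop("acinus radii must be positive")
  bad <- acini$row - acini$radius < 0 |
    acini$row + acini$radius > lattice_rows - 1 |
    acini$col - acini$radius < 0 |
    acini$col + acini$radius > lattice_cols - 1
  if (any(bad)) stop("acinus outside lattice")
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(programs))
    programs <- default_programs(gene_ids, stage_breaks, stage_names)
  if (is.null(background_domains))
    background_domains <- default_background(gene_ids, programs)
  if (nrow(programs) == 0L) stop("empty program list")
  prog_genes <- c(programs$gene, background_domains$gene)
  if (anyDuplicated(prog_genes))
    stop("program gene lists must be disjoint within a gland type")
  if (!all(prog_genes %in% gene_ids)) stop("program gene not in universe")
  if (!all(is.finite(programs$amplitude)) ||
      !all(is.finite(programs$midpoint)))
    stop("effect sizes and midpoints must be finite")
  if (!all(programs$stage %in% stage_names)) stop("unknown program stage")
  if (library_size <= 0) stop("library_size must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  cells_per_spot <- as.integer(cells_per_spot)
  if (length(cells_per_spot) == 1L) cells_per_spot <- rep(cells_per_spot, 2L)
  structure(list(lattice_rows = as.integer(lattice_rows),
                 lattice_cols = as.integer(lattice_cols),
                 acini = acini, stage_breaks = stage_breaks,
                 stage_names = stage_names, programs = programs,
                 background_domains = background_domains,
                 gene_ids = gene_ids,
                 cells_per_spot = cells_per_spot,
                 library_size = library_size, dispersion = dispersion,
                 baseline_sd = baseline_sd, sigmoid_tau = sigmoid_tau,
                 depth_jitter_sd = depth_jitter_sd,
                 seed = as.integer(seed)),
            class = "GlandSpec")
}

#' Stage bands implied by stage breaks
#' @param stage_breaks increasing break points in (0,1).
#' @return data frame with columns `lo`, `hi`, `center`, one row per stage.
#' @export
stage_bands <- function(stage_breaks) {
  lo <- c(0, stage_breaks)
  hi <- c(stage_breaks, 1)
  data.frame(lo = lo, hi = hi, center = (lo + hi) / 2)
}

#' Stage index of a depth value
#' @param d radial depth in `[0,1]`.
#' @param stage_breaks increasing break points in (0,1).
#' @return integer stage index (1 = most basal).
#' @export
stage_of <- function(d, stage_breaks) {
  findInterval(d, stage_breaks, left.open = FALSE) + 1L
}

# Default maturation programs: energy metabolism early, lipid metabolism
# intermediate, keratinization/duct late; 150 genes each, midpoints spread
# evenly within the stage band.
default_programs <- function(gene_ids, stage_breaks, stage_names,
                             n_per_stage = 150L, amplitude = 2.5) {
  bands <- stage_bands(stage_breaks)
  n_stages <- nrow(bands)
  out <- vector("list", n_stages)
  idx <- 0L
  for (s in seq_len(n_stages)) {
    g <- gene_ids[idx + seq_len(n_per_stage)]
    idx <- idx + n_per_stage
    w <- bands$hi[s] - bands$lo[s]
    mid <- seq(bands$lo[s] + 0.15 * w, bands$hi[s] - 0.15 * w,
               length.out = n_per_stage)
    out[[s]] <- data.frame(gene = g, stage = stage_names[s],
                           amplitude = amplitude, midpoint = mid)
  }
  do.call(rbind, out)
}

# Default non-gland domains: stroma, epidermis, muscle; 100 genes each.
default_background <- function(gene_ids, programs, n_per_domain = 100L,
                               amplitude = 2.5) {
  pool <- setdiff(gene_ids, programs$gene)
  domains <- c("STROMA", "EPI", "MUSC")
  data.frame(gene = pool[seq_len(n_per_domain * length(domains))],
             domain = rep(domains, each = n_per_domain),
             amplitude = amplitude)
}

sigmoid_activation <- function(d, midpoint, tau) {
  stats::plogis((d - midpoint) / tau)
}

#' Generate a synthetic gland section
#'
#' Draws a Visium-like section from a [gland_spec()]: spots on a rectangular
#' lattice, concentric maturation layers inside each acinus, non-gland domains
#' elsewhere, per-spot mixing of several cells (depth jitter), and
#' overdispersed counts. Identical spec + seed reproduces identical output.
#'
#' @param spec a `GlandSpec`.
#' @param keep_intensity keep the noiseless expected count-fraction matrix in
#'   the ground truth (genes x spots, dense); the test oracle for the
#'   generative model.
#' @return list with elements `dataset` (a [spot_dataset()]) and `truth`, a
#'   list with `spots` (spot_id, domain, d, acinus), `genes` (gene_id,
#'   program, stage, midpoint, amplitude) and optionally `expected_fraction`.
#' @export
generate_gland_section <- function(spec, keep_intensity = TRUE) {
  stopifnot(inherits(spec, "GlandSpec"))
  withr::with_seed(spec$seed, generate_section_impl(spec, keep_intensity))
}

generate_section_impl <- function(spec, keep_intensity) {
  nr <- spec$lattice_rows; nc <- spec$lattice_cols
  grid <- expand.grid(array_row = seq_len(nr) - 1L,
                      array_col = seq_len(nc) - 1L)
  n_spots <- nrow(grid)
  spot_ids <- sprintf("S%05d", seq_len(n_spots))

  # radial depth within the nearest covering acinus
  d <- rep(NA_real_, n_spots)
  acinus <- rep(NA_integer_, n_spots)
  for (a in seq_len(nrow(spec$acini))) {
    dist <- sqrt((grid$array_row - spec$acini$row[a])^2 +
                   (grid$array_col - spec$acini$col[a])^2)
    inside <- dist <= spec$acini$radius[a] & is.na(d)
    d[inside] <- 1 - dist[inside] / spec$acini$radius[a]
    acinus[inside] <- a
  }
  gland <- !is.na(d)

  domain <- character(n_spots)
  domain[gland] <- spec$stage_names[stage_of(d[gland], spec$stage_breaks)]
  bg_names <- unique(spec$background_domains$domain)
  band <- findInterval(grid$array_col,
                       seq(0, nc, length.out = length(bg_names) + 1L),
                       rightmost.closed = TRUE, left.open = TRUE)
  band[band < 1L] <- 1L
  domain[!gland] <- bg_names[band[!gland]]

  genes <- spec$gene_ids
  n_genes <- length(genes)
  baseline <- stats::rnorm(n_genes, 0, spec$baseline_sd)
  lambda <- matrix(exp(baseline), n_genes, n_spots)

  # gland spots: average the activation intensity over cells_per_spot cells
  # whose depths jitter around the spot depth (55 um spot mixing)
  gl_idx <- which(gland)
  if (length(gl_idx) > 0L && nrow(spec$programs) > 0L) {
    ncell <- sample(seq(spec$cells_per_spot[1], spec$cells_per_spot[2]),
                    length(gl_idx), replace = TRUE)
    cell_spot <- rep(seq_along(gl_idx), ncell)
    d_cell <- pmin(pmax(d[gl_idx][cell_spot] +
                          stats::rnorm(length(cell_spot), 0,
                                       spec$depth_jitter_sd), 0), 1)
    mrow <- match(spec$programs$gene, genes)
    act <- sigmoid_activation(
      matrix(d_cell, nrow(spec$programs), length(d_cell), byrow = TRUE),
      spec$programs$midpoint, spec$sigmoid_tau)
    eact <- exp(act * spec$programs$amplitude)
    # per-spot mean over cells
    agg <- t(rowsum(t(eact), group = cell_spot)) /
      matrix(ncell, nrow(eact), length(gl_idx), byrow = TRUE)
    lambda[mrow, gl_idx] <- lambda[mrow, gl_idx] * agg
  }

  # background domain programs: binary activation in their domain
  for (dm in bg_names) {
    rows <- match(spec$background_domains$gene[
      spec$background_domains$domain == dm], genes)
    cols <- which(domain == dm & !gland)
    if (length(rows) && length(cols))
      lambda[rows, cols] <- lambda[rows, cols] *
        exp(spec$background_domains$amplitude[
          spec$background_domains$domain == dm])
  }

  frac <- sweep(lambda, 2, colSums(lambda), "/")
  mu <- spec$library_size * frac
  counts <- if (spec$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
           n_genes, n_spots)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), n_genes, n_spots)
  }

  positions <- data.frame(spot_id = spot_ids, in_tissue = 1L,
                          array_row = grid$array_row,
                          array_col = grid$array_col,
                          pxl_row = grid$array_row * 100,
                          pxl_col = grid$array_col * 100)
  ds <- spot_dataset(counts, genes, spot_ids, positions,
                     labels = stats::setNames(domain, spot_ids))

  gene_truth <- data.frame(gene_id = genes, program = "none",
                           stage = NA_character_, midpoint = NA_real_,
                           amplitude = 0)
  pi <- match(spec$programs$gene, genes)
  gene_truth$program[pi] <- spec$programs$stage
  gene_truth$stage[pi] <- spec$programs$stage
  gene_truth$midpoint[pi] <- spec$programs$midpoint
  gene_truth$amplitude[pi] <- spec$programs$amplitude
  bi <- match(spec$background_domains$gene, genes)
  gene_truth$program[bi] <- spec$background_domains$domain
  gene_truth$amplitude[bi] <- spec$background_domains$amplitude

  truth <- list(
    spots = data.frame(spot_id = spot_ids, domain = domain, d = d,
                       acinus = acinus),
    genes = gene_truth)
  if (keep_intensity) {
    dimnames(frac) <- list(genes, spot_ids)
    truth$expected_fraction <- frac
  }
  list(dataset = ds, truth = truth)
}

#' Generate a paired two-gland experiment with a planted stage shift
#'
#' Builds two sections over the same gene universe. A seeded Bernoulli draw
#' flags a `shared_fraction` of gland A's maturation genes as shared; shared
#' genes reappear in gland B's programs with their activation midpoint moved
#' to the center of the stage band `stage_shift` stages later (clamped to the
#' last stage). Gland B's remaining program slots are filled with fresh genes
#' from the non-program pool. The planted stage-correspondence table is
#' returned as ground truth.
#'
#' @param specA,specB `GlandSpec` objects over identical gene universes.
#' @param shared_fraction probability a maturation gene of A is shared.
#' @param stage_shift integer stage displacement applied to shared genes in B.
#' @param seed seed for the sharing draw (sections use their own spec seeds).
#' @return list with `datasetA`, `datasetB`, `truth` (list of `A`, `B`
#'   section truths and `genes`, the correspondence table with columns
#'   `gene`, `shared`, `stage_A`, `stage_idx_A`, `stage_B`, `stage_idx_B`).
#' @export
generate_two_gland_experiment <- function(specA, specB, shared_fraction,
                                          stage_shift = 0L, seed = 1L) {
  stopifnot(inherits(specA, "GlandSpec"), inherits(specB, "GlandSpec"))
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must be in [0,1]")
  if (!identical(specA$gene_ids, specB$gene_ids))
    stop("the two specs must share one gene universe")
  nB <- length(specB$stage_breaks) + 1L
  bandsB <- stage_bands(specB$stage_breaks)

  progA <- specA$programs
  withr::with_seed(seed, {
    shared <- stats::runif(nrow(progA)) < shared_fraction
    idxA <- stage_of(progA$midpoint, specA$stage_breaks)
    idxB <- pmin(pmax(idxA + stage_shift, 1L), nB)
    progB_shared <- data.frame(gene = progA$gene[shared],
                               stage = specB$stage_names[idxB[shared]],
                               amplitude = progA$amplitude[shared],
                               midpoint = bandsB$center[idxB[shared]])
    # unique-to-B genes drawn from the unused pool, one per unshared A gene,
    # spread over B's stages
    pool <- setdiff(specA$gene_ids,
                    c(progA$gene, specA$background_domains$gene,
                      specB$background_domains$gene))
    n_unique <- sum(!shared)
    if (n_unique > length(pool)) stop("gene universe too small for unique genes")
    ug <- sample(pool, n_unique)
    ustage <- rep_len(seq_len(nB), n_unique)
    progB_unique <- if (n_unique > 0L) data.frame(
      gene = ug, stage = specB$stage_names[ustage],
      amplitude = if (nrow(progA)) mean(progA$amplitude) else 2.5,
      midpoint = bandsB$lo[ustage] +
        stats::runif(n_unique, 0.15, 0.85) *
        (bandsB$hi[ustage] - bandsB$lo[ustage]))
    else progA[0, ]
  })
  progB <- rbind(progB_shared, progB_unique)
  specB$programs <- progB[order(progB$gene), , drop = FALSE]
  rownames(specB$programs) <- NULL

  secA <- generate_gland_section(specA)
  secB <- generate_gland_section(specB)
  corr <- data.frame(gene = progA$gene, shared = shared,
                     stage_A = specA$stage_names[idxA], stage_idx_A = idxA,
                     stage_B = ifelse(shared, specB$stage_names[idxB], NA),
                     stage_idx_B = ifelse(shared, idxB, NA))
  list(datasetA = secA$dataset, datasetB = secB$dataset,
       truth = list(A = secA$truth, B = secB$truth, genes = corr))
}
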