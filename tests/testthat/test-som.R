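test_that("train_som returns a sound model and is seed-deterministic", {
  x <- toy_som_input()
  m1 <- train_som(x, grid_rows = 4L, grid_cols = 4L, epochs = 5L, seed = 2L,
                  var_keep = 1)
  m2 <- train_som(x, grid_rows = 4L, grid_cols = 4L, epochs = 5L, seed = 2L,
                  var_keep = 1)
  expect_identical(m1$codebook, m2$codebook)
  expect_identical(m1$gene_assignment, m2$gene_assignment)
  expect_equal(dim(m1$codebook), c(16L, 20L))
  expect_equal(length(m1$gene_assignment), 60L)
  expect_equal(nrow(m1$log), 5L)
  expect_true(all(m1$gene_assignment >= 1 & m1$gene_assignment <= 16))
  expect_error(train_som(x, grid_rows = 0L), "grid")
})

test_that("the variance filter keeps the requested gene fraction", {
  x <- toy_som_input(40L, 10L)
  m <- train_som(x, grid_rows = 3L, grid_cols = 3L, epochs = 3L,
                 var_keep = 0.5)
  expect_equal(length(m$gene_assignment), 20L)
})

test_that("a 1x1 SOM converges to the centered gene-profile mean", {
  x <- toy_som_input(20L, 8L)
  m <- train_som(x, grid_rows = 1L, grid_cols = 1L, epochs = 3L,
                 var_keep = 1)
  z <- x$values - rowMeans(x$values)
  expect_equal(as.vector(m$codebook), unname(colMeans(z)), tolerance = 1e-10)
  expect_equal(unname(m$gene_assignment), rep(1L, 20))
})

test_that("identical gene profiles share a best-matching node", {
  prof <- withr::with_seed(6L, rnorm(10))
  v <- rbind(matrix(rep(prof, each = 5), 5, 10),
             matrix(rep(-prof, each = 5), 5, 10))
  x <- toy_expr(v)
  m <- train_som(x, grid_rows = 4L, grid_cols = 4L, epochs = 10L,
                 var_keep = 1)
  a <- m$gene_assignment
  expect_equal(length(unique(a[1:5])), 1L)
  expect_equal(length(unique(a[6:10])), 1L)
  expect_false(a[1] == a[6])
})

test_that("anticorrelated gene groups land far apart on the grid", {
  x <- toy_som_input(seed = 3L)
  m <- train_som(x, grid_rows = 8L, grid_cols = 8L, epochs = 20L,
                 var_keep = 1)
  co <- m$node_coords[m$gene_assignment, , drop = FALSE]
  c1 <- colMeans(co[1:30, , drop = FALSE])
  c2 <- colMeans(co[31:60, , drop = FALSE])
  expect_gt(sqrt(sum((c1 - c2)^2)), 3)
})

test_that("spot portraits reshape codebook columns column-major", {
  x <- toy_som_input()
  m <- train_som(x, grid_rows = 3L, grid_cols = 4L, epochs = 3L,
                 var_keep = 1)
  p <- spot_portrait(m, "S5")
  expect_s3_class(p, "Portrait")
  expect_equal(dim(p), c(3L, 4L))
  j <- match("S5", m$spots)
  expect_equal(unclass(p)[2, 3], unname(m$codebook[(3 - 1) * 3 + 2, j]))
  expect_equal(as.vector(unclass(p)), unname(m$codebook[, j]))
  expect_error(spot_portrait(m, "nope"), "unknown spot")
})

test_that("mean portraits are elementwise means of spot portraits", {
  x <- toy_som_input()
  m <- train_som(x, grid_rows = 3L, grid_cols = 3L, epochs = 3L,
                 var_keep = 1)
  spots <- c("S1", "S4", "S9")
  mp <- mean_portrait(m, spots, subject = "grp")
  avg <- Reduce(`+`, lapply(spots, function(s)
    unclass(spot_portrait(m, s)))) / 3
  expect_equal(unclass(mp), avg, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(mp, "subject"), "grp")
  expect_error(mean_portrait(m, character(0)), "empty spot set")
  expect_error(mean_portrait(m, "nope"), "unknown")
})

test_that("difference portraits are antisymmetric and vanish on identity", {
  p1 <- fake_portrait(matrix(1:6 / 7, 2, 3))
  p2 <- fake_portrait(matrix(rev(1:6) / 5, 2, 3))
  d12 <- difference_portrait(p1, p2)
  d21 <- difference_portrait(p2, p1)
  expect_equal(unclass(d12), -unclass(d21), ignore_attr = TRUE)
  expect_true(all(unclass(difference_portrait(p1, p1)) == 0))
  expect_error(difference_portrait(p1, fake_portrait(matrix(0, 3, 2))),
               "mismatch")
})

test_that("detect_modules finds connected overexpressed blocks", {
  # 4x4 grid, column-major node index: top-left 2x2 block = nodes 1,2,5,6;
  # far corner (4,4) = node 16, not adjacent to the block
  assign <- stats::setNames(c(1L, 2L, 5L, 6L, 16L, 16L, 3L, 11L),
                            paste0("g", 1:8))
  m <- fake_som(4L, 4L, assign)
  block <- matrix(0, 4, 4); block[1:2, 1:2] <- 1
  corner <- matrix(0, 4, 4); corner[4, 4] <- 1
  p1 <- fake_portrait(block)
  p2 <- fake_portrait(block + corner)
  mods <- detect_modules(m, list(a = p1, b = p2),
                         overexpression_quantile = 0.8, min_support = 2L)
  expect_length(mods, 1L)
  expect_setequal(mods[[1]]$node_idx, c(1L, 2L, 5L, 6L))
  expect_setequal(mods[[1]]$genes, paste0("g", 1:4))
  expect_setequal(mods[[1]]$support, c("a", "b"))
  expect_equal(mods[[1]]$label, "A")

  mods1 <- detect_modules(m, list(a = p1, b = p2),
                          overexpression_quantile = 0.8, min_support = 1L)
  expect_length(mods1, 2L)
  expect_equal(unname(vapply(mods1, `[[`, "", "label")), c("A", "B"))
  # labels order by decreasing gene count: block has 4 genes, corner 2
  expect_setequal(mods1[[2]]$node_idx, 16L)
  expect_setequal(mods1[[2]]$genes, c("g5", "g6"))
  expect_equal(mods1[[2]]$support, "b")

  expect_length(detect_modules(m, list(p1), 0.8, min_support = 3L), 0L)
  expect_error(detect_modules(m, list(), 0.9, 1L), "portrait")
  expect_error(detect_modules(m, list(p1), 1.2, 1L), "quantile")
})

test_that("diagonal components merge under 8- but not 4-adjacency", {
  assign <- stats::setNames(c(1L, 5L), c("g1", "g2"))
  m <- fake_som(3L, 3L, assign)
  diagp <- matrix(0, 3, 3); diagp[1, 1] <- 1; diagp[2, 2] <- 1
  p <- fake_portrait(diagp)
  m8 <- detect_modules(m, list(p), 0.9, 1L, adjacency = 8)
  m4 <- detect_modules(m, list(p), 0.9, 1L, adjacency = 4)
  expect_length(m8, 1L)
  expect_length(m4, 2L)
})

test_that("submodule_split separates signed parts of a difference", {
  assign <- stats::setNames(c(1L, 2L, 4L, 5L), paste0("g", 1:4))
  m <- fake_som(3L, 3L, assign)
  block <- matrix(0, 3, 3); block[1:2, 1:2] <- 1
  parent <- detect_modules(m, list(fake_portrait(block)), 0.6, 1L)[[1]]
  d <- matrix(0, 3, 3)
  d[1, 1] <- 2            # node 1: positive
  d[2, 2] <- -3           # node 5: negative
  subs <- submodule_split(m, parent, fake_portrait(d), quantile = 0.5)
  signs <- vapply(subs, `[[`, 1, "sign")
  expect_setequal(signs, c(1, -1))
  pos <- subs[[which(signs == 1)]]
  neg <- subs[[which(signs == -1)]]
  expect_equal(pos$node_idx, 1L)
  expect_equal(pos$genes, "g1")
  expect_equal(pos$label, "A+1")
  expect_equal(neg$node_idx, 5L)
  expect_equal(neg$genes, "g4")
  expect_equal(neg$label, "A-1")
})

test_that("module_expression scores spots by member-gene means", {
  ds <- toy_dataset(6L, 4L, seed = 9L)
  x <- normalize_log(ds)
  mod <- structure(list(label = "A", node_idx = 1L,
                        nodes = cbind(row = 1L, col = 1L),
                        genes = c("g2", "g5"), support = "a"),
                   class = "ModuleDef")
  me <- module_expression(ds, x, mod)
  expect_equal(me$spot_id, ds$spot_ids)
  expect_equal(me$score, unname(colMeans(x$values[c("g2", "g5"), ])))
  mod$genes <- "absent"
  expect_error(module_expression(ds, x, mod), "no module gene")
})

test_that("co_appearance_map counts joint overexpression fractions", {
  assign <- stats::setNames(c(1L, 9L), c("g1", "g2"))
  m <- fake_som(3L, 3L, assign)
  block <- matrix(0, 3, 3); block[1, 1] <- 1
  corner <- matrix(0, 3, 3); corner[3, 3] <- 1
  mods <- list(
    structure(list(label = "A", node_idx = 1L, genes = "g1",
                   nodes = cbind(row = 1L, col = 1L), support = character(0)),
              class = "ModuleDef"),
    structure(list(label = "B", node_idx = 9L, genes = "g2",
                   nodes = cbind(row = 3L, col = 3L), support = character(0)),
              class = "ModuleDef"))
  center <- matrix(-2, 3, 3); center[2, 2] <- -1
  ports <- list(fake_portrait(block),            # A only
                fake_portrait(block + corner),   # A and B
                fake_portrait(corner),           # B only
                fake_portrait(center))           # neither at q = 0.9
  co <- co_appearance_map(ports, mods, overexpression_quantile = 0.9)
  expect_equal(co["A", "A"], 2 / 4)
  expect_equal(co["B", "B"], 2 / 4)
  expect_equal(co["A", "B"], 1 / 4)
  expect_equal(co, t(co))
  expect_error(co_appearance_map(ports, list()), "empty module list")
})

test_that("detect_stage_modules resolves cumulative stage programs", {
  # Hand-built cumulative trajectory on a 4x4 grid, one spot per domain:
  # earlier programs stay on in later stages, so the later domain portraits
  # are topped by earlier-stage nodes; the stage-aware battery must still
  # isolate the interior program (rising across both transitions) and the
  # terminal one (late jump, caught by the curvature portrait).
  cb <- matrix(0, 16, 4, dimnames = list(NULL, c("S1", "S2", "S3", "S4")))
  nB <- c(1L, 2L); nD <- c(5L, 6L); nU <- c(11L, 12L); nBG <- c(15L, 16L)
  cb[nB, ] <- rep(c(1, 1.1, 1.15, 0), each = 2)    # saturates early
  cb[nD, ] <- rep(c(0, 0.8, 1.6, 0), each = 2)     # rises at both steps
  cb[nU, ] <- rep(c(0, 0.05, 1, 0), each = 2)      # jumps late
  cb[nBG, ] <- rep(c(0, 0, 0, 1), each = 2)
  assign <- stats::setNames(c(nB, nD, nU, nBG),
                            c("b1", "b2", "d1", "d2", "u1", "u2",
                              "bg1", "bg2"))
  m <- fake_som(4L, 4L, assign, n_spots = 4L, codebook = cb)
  labels <- stats::setNames(c("B", "D", "U", "BG"), colnames(cb))
  mods <- detect_stage_modules(m, labels, stages = c("B", "D", "U"))
  srcs <- vapply(mods, `[[`, "", "source")
  expect_true(any(grepl("^domain_", srcs)))
  expect_true(any(grepl("^transit_D", srcs)))
  expect_true(any(grepl("^terminal_U", srcs)))
  # the later domain portraits are topped by earlier-stage nodes...
  dom_u <- mods[srcs == "domain_U"][[1]]
  expect_setequal(dom_u$genes, c("d1", "d2"))
  # ...yet every program is recovered exactly by its dedicated call
  planted <- list(b = c("b1", "b2"), d = c("d1", "d2"),
                  u = c("u1", "u2"), bg = c("bg1", "bg2"))
  for (p in planted)
    expect_equal(f1_best(p, mods), 1)
  transit <- mods[grepl("^transit_D", srcs)][[1]]
  expect_setequal(transit$genes, c("d1", "d2"))
  term <- mods[srcs == "terminal_U"][[1]]
  expect_setequal(term$genes, c("u1", "u2"))
  labs <- vapply(mods, `[[`, "", "label")
  expect_equal(anyDuplicated(labs), 0L)
  expect_error(detect_stage_modules(m, unname(labels), c("B", "D", "U")),
               "named")
  expect_error(detect_stage_modules(m, labels, c("B", "D", "X")),
               "stage without labeled spots")
})
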