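test_that("generators are deterministic under a fixed seed", {
  cfg <- synth_config(seed = 17, n_cells = 300L)
  a <- make_cell_table(cfg); b <- make_cell_table(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$true_type, b$true_type)
  expect_identical(make_spot_expression(cfg), make_spot_expression(cfg))
  pa <- make_image_pair(cfg); pb <- make_image_pair(cfg)
  expect_identical(pa$fixed, pb$fixed)
  expect_identical(pa$moving, pb$moving)
})

test_that("planted type frequencies follow the configured proportions", {
  cfg <- synth_config(seed = 1, n_cells = 1000L, spatial_layout = "uniform",
                      type_proportions = c("Tumor" = 0.6,
                                           "CD8 T cells" = 0.4))
  gen <- make_cell_table(cfg)
  expect_equal(nrow(gen$cells), 1000L)
  tally <- table(gen$true_type)
  expect_lt(abs(tally[["Tumor"]] - 600), 60)       # ~4 binomial sd
  expect_error(make_cell_table(synth_config(
    type_proportions = c("NotAType" = 1))), "unknown type")
})

test_that("zero marker separation collapses typing to chance", {
  cfg <- synth_config(seed = 2, n_cells = 400L, mu_pos = log(5),
                      mu_neg = log(5))
  gen <- make_cell_table(cfg)
  ann <- annotate_cells(log_transform(gen$cells), load_registry("paper17"))
  expect_lt(mean(ann$cell_type == gen$true_type), 0.5)
})

test_that("image-pair landmarks track the configured transform exactly", {
  idp <- make_image_pair(synth_config(seed = 3))
  expect_equal(idp$landmarks_moving, idp$landmarks_fixed)

  sh <- make_image_pair(synth_config(seed = 3, shift_px = c(10, -7)))
  d <- sh$landmarks_fixed - sh$landmarks_moving
  expect_equal(unname(d[, 1]), rep(10, nrow(d)))
  expect_equal(unname(d[, 2]), rep(-7, nrow(d)))

  th <- 8 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- make_image_pair(synth_config(seed = 3, rotation_deg = 8))
  ctr <- (synth_config()$image_size + 1) / 2
  want <- t(R %*% t(sweep(rot$landmarks_moving, 2, c(ctr, ctr)))) +
    rep(c(ctr, ctr), each = nrow(rot$landmarks_moving))
  expect_equal(rot$landmarks_fixed, want, tolerance = 1e-10)
  # the forward function agrees with the landmark bookkeeping
  expect_equal(rot$forward(rot$landmarks_moving), rot$landmarks_fixed,
               tolerance = 1e-8)
})

test_that("the spot grid is hexagonal, non-overlapping and 55 um by default", {
  cfg <- synth_config(grid_rows = 10L, grid_cols = 10L)
  spots <- make_spot_grid(cfg)
  expect_equal(nrow(spots), 100L)
  expect_false(anyDuplicated(spots$barcode) > 0)
  dmin <- min(stats::dist(cbind(spots$x, spots$y))) *
    attr(spots, "microns_per_pixel")
  expect_equal(dmin, 100, tolerance = 1e-9)
  expect_equal(attr(spots, "diameter_um"), 55)
  expect_gt(dmin, attr(spots, "diameter_um"))  # discs never overlap
})

test_that("hotspot expression boosts the planted pair only inside the disc", {
  null_cfg <- synth_config(seed = 9, fold_change = 1)
  spots <- make_spot_grid(null_cfg)
  m0 <- make_spot_expression(null_cfg, spots)
  hot <- attr(m0, "hotspot_spots")
  cold <- setdiff(rownames(m0), hot)
  # null: no difference beyond sampling noise (~4 standard errors)
  se <- sqrt(stats::var(m0[, "LIG1"]) * (1 / length(hot) + 1 / length(cold)))
  expect_lt(abs(mean(m0[hot, "LIG1"]) - mean(m0[cold, "LIG1"])), 4 * se)

  hot_cfg <- synth_config(seed = 9, fold_change = 8)
  m8 <- make_spot_expression(hot_cfg, spots)
  nb <- build_neighbor_graph(spots, "radius", 150)
  s <- lr_spot_scores(normalize_expression(m8),
                      list(ligand = "LIG1", receptor = "REC1"), nb)
  expect_gt(mean(s[hot]), 2 * mean(s[cold]))
})

test_that("synthetic data round-trips through the file formats", {
  dir <- tempfile("synthio_")
  files <- simulate_preset("lrhotspot", seed = 2, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("positions.csv", "counts.mtx",
                                               "lr_pairs.tsv")))))
  spots <- read_spot_positions(file.path(dir, "positions.csv"),
                               microns_per_pixel = 5)
  counts <- read_counts(file.path(dir, "counts.mtx"))
  orig <- make_spot_expression(synth_config(seed = 2, fold_change = 8))
  expect_equal(counts[rownames(orig), colnames(orig)], orig,
               ignore_attr = TRUE)
  expect_setequal(spots$barcode, rownames(orig))

  dir2 <- tempfile("synthio_")
  simulate_preset("celltyping", seed = 4, out_dir = dir2)
  back <- read_cell_table(file.path(dir2, "cells.csv"),
                          microns_per_pixel = 5)
  orig2 <- make_cell_table(synth_config(seed = 4))$cells
  expect_equal(as.data.frame(back), as.data.frame(orig2), tolerance = 1e-12)

  reg <- load_registry("paper17")
  tmp <- tempfile(fileext = ".tsv")
  write_registry(reg, tmp)
  reg2 <- load_registry(tmp)
  expect_equal(reg2$type_name, reg$type_name)
  expect_equal(reg2$markers, reg$markers)
})
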