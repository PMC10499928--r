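#' Synthetic-data configuration
#'
#' Every pipeline input can be generated with known ground truth: a
#' segmented-cell table with planted type labels, an image pair related by a
#' known affine (plus optional smooth deformation), a hexagonal spot grid,
#' and a spot x gene count matrix with an optionally planted co-expressed
#' ligand-receptor hotspot.  All generators are deterministic given `seed`.
#'
#' Marker intensities follow a log-normal stain model: markers belonging to
#' the cell's type subset draw from `LogNormal(mu_pos, sigma)`, all others
#' from `LogNormal(mu_neg, sigma)`.  The defaults put the two populations
#' about five log-sd apart, emulating a clean, well-separated stain.
#'
#' @param seed RNG seed
#' @param n_cells number of cells
#' @param type_proportions named fractions over registry type names
#'   (must sum to 1)
#' @param mu_pos,mu_neg log-scale means of positive / negative markers
#' @param sigma log-scale sd of both populations
#' @param spatial_layout `"regions"` (default) lays the section out as a
#'   tumor-enriched and an immune-enriched half, emulating the contiguous
#'   architecture a pathologist can annotate; `"uniform"` mixes types
#'   independently of position
#' @param region_purity probability that a cell in a region belongs to the
#'   region's lineage (layout `"regions"`)
#' @param image_size side of the square synthetic images, pixels
#' @param n_blobs number of Gaussian "nuclei" blobs
#' @param rotation_deg,shift_px,scale true affine from moving to fixed
#'   coordinates (rotation about the image centre; `shift_px` length-2)
#' @param deform_amp_px amplitude of an optional smooth sinusoidal
#'   deformation (0 = pure affine)
#' @param noise_sd additive Gaussian pixel noise on the moving image
#' @param grid_rows,grid_cols spot grid dimensions
#' @param pitch_um centre-to-centre spot distance (standard array: 100)
#' @param diameter_um spot capture diameter (default 55)
#' @param microns_per_pixel scale tying the grid to the fixed image
#' @param n_genes genes in the synthetic count matrix
#' @param nb_mean,nb_dispersion negative-binomial count model (dispersion is
#'   the `size` parameter)
#' @param lr_pair `c(ligand, receptor)` gene names to plant
#' @param hotspot_center,hotspot_radius_um disc (in microns, grid
#'   coordinates) where the planted pair is boosted
#' @param fold_change mean multiplier of the planted pair inside the
#'   hotspot (1 = null data)
#' @return a `spici_synthconfig` list
#' @export
synth_config <- function(seed = 1L,
                         n_cells = 2000L,
                         type_proportions = c(
                           "Tumor" = 0.45,
                           "CD8 T cells" = 0.15,
                           "CD4 T cells" = 0.15,
                           "B-cell" = 0.10,
                           "Macrophage/monocyte" = 0.10,
                           "Antigen-presenting cells" = 0.05),
                         mu_pos = log(30), mu_neg = log(0.2), sigma = 0.5,
                         spatial_layout = c("regions", "uniform"),
                         region_purity = 0.85,
                         image_size = 256L, n_blobs = 40L,
                         rotation_deg = 0, shift_px = c(0, 0), scale = 1,
                         deform_amp_px = 0, noise_sd = 0.02,
                         grid_rows = 10L, grid_cols = 10L,
                         pitch_um = 100, diameter_um = 55,
                         microns_per_pixel = 5,
                         n_genes = 500L, nb_mean = 5, nb_dispersion = 2,
                         lr_pair = c("LIG1", "REC1"),
                         hotspot_center = NULL, hotspot_radius_um = 250,
                         fold_change = 1) {
  spatial_layout <- match.arg(spatial_layout)
  stopifnot(abs(sum(type_proportions) - 1) < 1e-8,
            n_cells >= 1L, n_genes >= 2L, mu_pos >= mu_neg,
            region_purity >= 0, region_purity <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "spici_synthconfig"
  cfg
}

#' Generate a synthetic segmented-cell table
#'
#' Cells are placed uniformly over the spot-grid footprint (in fixed-image
#' pixels); each draws a type from `type_proportions` and marker intensities
#' from the positive/negative log-normal model using the registry's
#' subsets.
#'
#' @param config a [synth_config()]
#' @param registry a `spici_registry` (default the built-in panel)
#' @return list: `cells` (raw `spici_cells`), `true_type` (planted labels),
#'   `true_spot` (barcode of the spot disc containing each cell, `NA` in
#'   gaps), `spots` (the grid used for placement)
#' @export
make_cell_table <- function(config = synth_config(),
                            registry = load_registry("paper17")) {
  unknown <- setdiff(names(config$type_proportions), registry$type_name)
  if (length(unknown)) stop("unknown type name: ", unknown[1L])
  set.seed(config$seed)
  spots <- make_spot_grid(config)
  n <- config$n_cells
  pad <- config$pitch_um / config$microns_per_pixel / 2
  xr <- range(spots$x) + c(-pad, pad)
  yr <- range(spots$y) + c(-pad, pad)
  x <- stats::runif(n, xr[1], xr[2])
  y <- stats::runif(n, yr[1], yr[2])
  prop <- config$type_proportions
  tnames <- names(prop)
  if (config$spatial_layout == "uniform") {
    types <- sample(tnames, n, replace = TRUE, prob = prop)
  } else {
    # two lateral regions: left tumor-enriched, right immune-enriched;
    # within a lineage, types keep their relative configured weights
    lin <- registry$lineage[match(tnames, registry$type_name)]
    w_tum <- ifelse(lin == "tumor", prop, 0)
    w_imm <- ifelse(lin == "tumor", 0, prop)
    if (sum(w_tum) == 0 || sum(w_imm) == 0) {
      types <- sample(tnames, n, replace = TRUE, prob = prop)
    } else {
      pur <- config$region_purity
      left <- x < mean(range(x))
      p_left <- pur * w_tum / sum(w_tum) + (1 - pur) * w_imm / sum(w_imm)
      p_right <- pur * w_imm / sum(w_imm) + (1 - pur) * w_tum / sum(w_tum)
      types <- character(n)
      types[left] <- sample(tnames, sum(left), replace = TRUE, prob = p_left)
      types[!left] <- sample(tnames, sum(!left), replace = TRUE,
                             prob = p_right)
    }
  }
  universe <- marker_universe(registry)
  X <- matrix(exp(stats::rnorm(n * length(universe), config$mu_neg,
                               config$sigma)),
              n, length(universe), dimnames = list(NULL, universe))
  for (tp in unique(types)) {
    rows <- which(types == tp)
    sub <- registry$markers[[match(tp, registry$type_name)]]
    X[rows, sub] <- exp(stats::rnorm(length(rows) * length(sub),
                                     config$mu_pos, config$sigma))
  }
  cells <- cell_table(sprintf("cell_%05d", seq_len(n)), x, y, X,
                      microns_per_pixel = config$microns_per_pixel)
  true_spot <- assign_cells_to_spots(
    structure(cells, class = class(cells)), spots)
  list(cells = cells, true_type = types, true_spot = true_spot, spots = spots)
}

#' Generate a synthetic registration image pair
#'
#' The fixed image is a field of Gaussian blobs ("nuclei"); the moving image
#' is the fixed image pulled through the configured true transform, plus
#' noise.  The true forward point map (moving to fixed pixels) is returned
#' both as a function and, when the deformation amplitude is zero, as a 2x3
#' affine; blob centres are tracked analytically in both frames as
#' landmarks.
#'
#' @param config a [synth_config()]
#' @return list: `fixed`, `moving` (matrices), `forward` (function
#'   `n x 2 -> n x 2`), `forward_affine` (2x3 or `NULL`), `inverse`
#'   (function), `landmarks_fixed`, `landmarks_moving` (n_blobs x 2)
#' @export
make_image_pair <- function(config = synth_config()) {
  set.seed(config$seed)
  sz <- config$image_size
  cx <- (sz + 1) / 2
  centers <- cbind(stats::runif(config$n_blobs, sz * 0.12, sz * 0.88),
                   stats::runif(config$n_blobs, sz * 0.12, sz * 0.88))
  sigmas <- stats::runif(config$n_blobs, 2.5, 6)
  amps <- stats::runif(config$n_blobs, 0.5, 1)
  xs <- seq_len(sz)
  fixed <- matrix(0, sz, sz)
  for (b in seq_len(config$n_blobs)) {
    gx <- exp(-(xs - centers[b, 1])^2 / (2 * sigmas[b]^2))
    gy <- exp(-(xs - centers[b, 2])^2 / (2 * sigmas[b]^2))
    fixed <- fixed + amps[b] * outer(gy, gx)
  }
  fixed <- fixed / max(fixed)
  th <- config$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  M <- R * config$scale
  tr <- c(cx, cx) + config$shift_px - M %*% c(cx, cx)
  G_affine <- cbind(M, tr)               # moving -> fixed
  amp <- config$deform_amp_px
  deform <- function(p)                  # smooth, analytically invertible-ish
    cbind(amp * sin(2 * pi * p[, 2] / sz), amp * cos(2 * pi * p[, 1] / sz))
  forward <- function(p) {
    p <- as.matrix(p)
    affine_apply(G_affine, p + deform(p))
  }
  inverse <- function(q) {
    q <- as.matrix(q)
    base <- affine_apply(affine_invert(G_affine), q)
    p <- base
    for (i in seq_len(20L)) p <- base - deform(p)
    p
  }
  moving <- resample_image(fixed, sz, sz, forward) +
    matrix(stats::rnorm(sz * sz, 0, config$noise_sd), sz, sz)
  moving[moving < 0] <- 0; moving[moving > 1] <- 1
  list(fixed = fixed, moving = moving,
       forward = forward,
       forward_affine = if (amp == 0) G_affine else NULL,
       inverse = inverse,
       landmarks_fixed = centers,
       landmarks_moving = inverse(centers))
}

#' Generate a hexagonal synthetic spot grid
#'
#' Standard array geometry: 100 um centre-to-centre pitch, 55 um capture
#' diameter, odd rows offset by half a pitch.  Centres are expressed in
#' fixed-image pixels via `microns_per_pixel`.
#'
#' @param config a [synth_config()]
#' @param origin_px pixel coordinate of the first spot centre
#' @return a `spici_spots` frame with synthetic barcodes
#' @export
make_spot_grid <- function(config = synth_config(), origin_px = c(20, 20)) {
  mpp <- config$microns_per_pixel
  pitch_px <- config$pitch_um / mpp
  rows <- config$grid_rows; cols <- config$grid_cols
  ij <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  x <- origin_px[1] + (ij$col - 1) * pitch_px +
    ifelse(ij$row %% 2 == 0, pitch_px / 2, 0)
  y <- origin_px[2] + (ij$row - 1) * pitch_px * sqrt(3) / 2
  spot_frame(sprintf("SYN-%03d-%03d", ij$row, ij$col), x, y,
             diameter_um = config$diameter_um, microns_per_pixel = mpp)
}

#' Generate a synthetic spot x gene count matrix
#'
#' Negative-binomial counts, exchangeable across genes, except that inside
#' the configured hotspot disc the planted ligand and receptor means are
#' multiplied by `fold_change` (1 = null data, no planted structure).
#'
#' @param config a [synth_config()]
#' @param spots a `spici_spots` frame (default the config's grid)
#' @return integer matrix, rows = barcodes, columns = genes (the planted
#'   pair first, then `g3 ... gN`); attribute `hotspot_spots` lists the
#'   barcodes inside the disc
#' @export
make_spot_expression <- function(config = synth_config(),
                                 spots = make_spot_grid(config)) {
  set.seed(config$seed + 1L)
  genes <- c(config$lr_pair, sprintf("g%03d", seq_len(config$n_genes - 2L)))
  n <- nrow(spots)
  mu <- matrix(config$nb_mean, n, config$n_genes,
               dimnames = list(spots$barcode, genes))
  center <- config$hotspot_center
  if (is.null(center)) center <- c(mean(spots$x), mean(spots$y))
  mpp <- attr(spots, "microns_per_pixel")
  d_um <- sqrt((spots$x - center[1])^2 + (spots$y - center[2])^2) * mpp
  hot <- d_um <= config$hotspot_radius_um
  if (config$fold_change != 1)
    mu[hot, config$lr_pair] <- mu[hot, config$lr_pair] * config$fold_change
  counts <- matrix(stats::rnbinom(n * config$n_genes, mu = mu,
                                  size = config$nb_dispersion),
                   n, config$n_genes, dimnames = dimnames(mu))
  attr(counts, "hotspot_spots") <- spots$barcode[hot]
  counts
}

#' Write a synthetic dataset preset to disk
#'
#' Emits the same file formats the pipeline reads: cell table CSV, spot
#' positions CSV, count matrix MTX (+ barcodes/features sidecars), L-R pair
#' TSV, and TIFF images, depending on the preset.
#'
#' @param preset one of `"celltyping"`, `"registration"`, `"endtoend"`,
#'   `"lrnull"`, `"lrhotspot"`
#' @param seed RNG seed
#' @param out_dir output directory (created)
#' @param config optional [synth_config()] overriding the preset's defaults
#' @return invisibly, the list of files written
#' @export
simulate_preset <- function(preset = c("celltyping", "registration",
                                       "endtoend", "lrnull", "lrhotspot"),
                            seed = 1L, out_dir, config = NULL) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config))
    config <- switch(preset,
      celltyping = synth_config(seed = seed),
      registration = synth_config(seed = seed, rotation_deg = 6,
                                  shift_px = c(9, -6), scale = 1.04),
      endtoend = synth_config(seed = seed, rotation_deg = 4,
                              shift_px = c(6, -4), scale = 1.02),
      lrnull = synth_config(seed = seed, fold_change = 1),
      lrhotspot = synth_config(seed = seed, fold_change = 8))
  files <- character(0)
  add <- function(p) files <<- c(files, p)
  if (preset %in% c("celltyping", "endtoend")) {
    ct <- make_cell_table(config)
    add(write_cell_table(ct$cells, file.path(out_dir, "cells.csv")))
    truth <- data.frame(cell_id = ct$cells$cell_id, true_type = ct$true_type,
                        true_spot = ct$true_spot)
    utils::write.table(truth, file.path(out_dir, "truth_cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add(file.path(out_dir, "truth_cells.tsv"))
    add(write_spot_positions(ct$spots, file.path(out_dir, "positions.csv")))
  }
  if (preset %in% c("registration", "endtoend")) {
    pair <- make_image_pair(config)
    add(write_image(pair$fixed, file.path(out_dir, "fixed.tif")))
    add(write_image(pair$moving, file.path(out_dir, "moving.tif")))
    lm <- data.frame(x_moving = pair$landmarks_moving[, 1],
                     y_moving = pair$landmarks_moving[, 2],
                     x_fixed = pair$landmarks_fixed[, 1],
                     y_fixed = pair$landmarks_fixed[, 2])
    utils::write.table(lm, file.path(out_dir, "landmarks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add(file.path(out_dir, "landmarks.tsv"))
  }
  if (preset %in% c("lrnull", "lrhotspot")) {
    spots <- make_spot_grid(config)
    add(write_spot_positions(spots, file.path(out_dir, "positions.csv")))
    counts <- make_spot_expression(config, spots)
    add(write_counts_mtx(counts, file.path(out_dir, "counts")))
    prs <- data.frame(ligand = config$lr_pair[1], receptor = config$lr_pair[2],
                      druggable = 1L, annotation = "synthetic")
    utils::write.table(prs, file.path(out_dir, "lr_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add(file.path(out_dir, "lr_pairs.tsv"))
  }
  invisible(files)
}
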