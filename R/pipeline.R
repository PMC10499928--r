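#' Pipeline configuration
#'
#' A single nested list tying the stages together: input paths (or
#' in-memory objects), per-stage settings and the output directory.  It can
#' be round-tripped through YAML for use from the command line.
#'
#' @param cells cell table path (CSV/TSV) or `spici_cells`
#' @param moving,fixed image paths or matrices for registration; `NULL`
#'   skips registration (cell coordinates are then taken as already being in
#'   fixed-image pixels)
#' @param spots spot-position path or `spici_spots`
#' @param truth optional named vector (or 2-column table path) of reference
#'   spot labels for evaluation
#' @param counts optional count matrix (path or matrix) for L-R ranking
#' @param lr_pairs optional pair-list path or data frame
#' @param out_dir artifact directory
#' @param registry registry source (default `"paper17"`)
#' @param mode annotation scoring mode
#' @param qc_lo,qc_hi quantile-filter bounds
#' @param min_features spot feature-count threshold
#' @param registration a [registration_config()]
#' @param groups optional dominant-type supergroup map
#' @param group_order optional tie-break order for supergroups
#' @param neighbor_radius_um neighbourhood radius for L-R scoring
#' @param n_background,alpha,adjust_method L-R test settings
#' @param seed seed for the L-R background draw
#' @return a `spici_config` list
#' @export
pipeline_config <- function(cells, spots, moving = NULL, fixed = NULL,
                            truth = NULL, counts = NULL, lr_pairs = NULL,
                            out_dir = tempfile("spici_run_"),
                            registry = "paper17",
                            mode = "product", qc_lo = 0.05, qc_hi = 0.95,
                            min_features = 200,
                            registration = registration_config(),
                            groups = NULL, group_order = NULL,
                            neighbor_radius_um = 150,
                            n_background = 1000L, alpha = 0.05,
                            adjust_method = "bonferroni", seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "spici_config"
  cfg
}

.load_or <- function(x, loader) if (is.character(x) && length(x) == 1L)
  loader(x) else x

.log_stage <- function(stage, ...) {
  message(sprintf("[spici] %-10s %s", stage, sprintf(...)))
}

#' Run the full integration pipeline
#'
#' Stages, in order: quantile QC and log scaling of the cell table;
#' marker-subset annotation; image registration (when images are supplied);
#' mapping of cell centroids into fixed-image coordinates; assignment of
#' cells to spots and per-spot composition; optional evaluation against
#' reference spot labels; optional ligand-receptor permutation ranking.
#' Each stage logs its input/output counts; any stage error aborts with the
#' stage named.  Artifacts (annotated cells, registration JSON, composition
#' TSV, evaluation JSON, rank TSV) are written under `config$out_dir`.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the main in-memory results
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }
  cells <- step("load", .load_or(config$cells, read_cell_table))
  spots <- step("load", .load_or(config$spots, read_spot_positions))
  registry <- step("load", .load_or(config$registry, identity))
  if (is.character(registry)) registry <- load_registry(registry)

  qc <- step("qc", filter_cells_quantile(cells, config$qc_lo, config$qc_hi))
  .log_stage("qc", "%d cells in, %d kept", qc$report$n_input, qc$report$n_kept)
  write_report_json(qc$report, file.path(config$out_dir, "qc_report.json"))
  cells <- step("qc", log_transform(qc$cells))

  cells <- step("annotate",
                annotate_cells(cells, registry, mode = config$mode))
  .log_stage("annotate", "%d cells typed (%d unclassified)", nrow(cells),
             sum(cells$cell_type == "Unclassified"))

  reg <- NULL
  if (!is.null(config$moving) && !is.null(config$fixed)) {
    moving <- .load_or(config$moving, read_image)
    fixed <- .load_or(config$fixed, read_image)
    prep <- step("register", prepare_images(moving, fixed,
                                            config$registration))
    reg <- step("register",
                register_pair(prep$moving, prep$fixed, config$registration))
    .log_stage("register", "MI %.3f -> %.3f (converged: %s)",
               reg$mi_before, reg$mi_after, reg$converged)
    write_registration(reg, file.path(config$out_dir, "registration.json"))
    cells <- step("transform", transform_cells(cells, reg))
  }
  write_cell_table(cells, file.path(config$out_dir, "annotated_cells.csv"))

  assignment <- step("assign", assign_cells_to_spots(cells, spots))
  .log_stage("assign", "%d / %d cells assigned to %d spots",
             sum(!is.na(assignment)), length(assignment), nrow(spots))
  comp <- step("composition",
               compute_composition(assignment, cells$cell_type, spots))
  write_composition(comp, file.path(config$out_dir, "composition.tsv"))
  labels <- step("composition",
                 dominant_type(comp, config$groups, config$group_order))

  evaluation <- NULL
  if (!is.null(config$truth)) {
    truth <- config$truth
    if (is.character(truth) && length(truth) == 1L) {
      tab <- utils::read.delim(truth, stringsAsFactors = FALSE)
      truth <- stats::setNames(tab[[2]], tab[[1]])
    }
    evaluation <- step("evaluate", evaluate_labels(labels, truth))
    .log_stage("evaluate", "accuracy %.3f on %d spots",
               evaluation$accuracy, evaluation$n_spots_compared)
    write_report_json(evaluation,
                      file.path(config$out_dir, "evaluation.json"))
  }

  lr <- rank_tab <- NULL
  if (!is.null(config$counts) && !is.null(config$lr_pairs)) {
    counts <- .load_or(config$counts, read_counts)
    pairs <- .load_or(config$lr_pairs, read_lr_pairs)
    flt <- step("lr-rank",
                filter_spots_min_features(counts, config$min_features))
    .log_stage("lr-rank", "%d / %d spots pass the %d-feature filter",
               flt$report$n_kept, flt$report$n_input, config$min_features)
    expr <- normalize_expression(flt$counts)
    sp_use <- spots[spots$barcode %in% rownames(expr), , drop = FALSE]
    attr(sp_use, "microns_per_pixel") <- attr(spots, "microns_per_pixel")
    attr(sp_use, "diameter_um") <- attr(spots, "diameter_um")
    class(sp_use) <- class(spots)
    nb <- step("lr-rank",
               build_neighbor_graph(sp_use, "radius",
                                    config$neighbor_radius_um))
    expr <- expr[sp_use$barcode, , drop = FALSE]
    lr <- step("lr-rank",
               permutation_pvalues(expr, pairs, nb,
                                   n_background = config$n_background,
                                   seed = config$seed, alpha = config$alpha,
                                   adjust_method = config$adjust_method))
    rank_tab <- rank_pairs(lr)
    utils::write.table(as.data.frame(rank_tab),
                       file.path(config$out_dir, "lr_rank.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .log_stage("lr-rank", "%d pairs ranked; top: %s", nrow(rank_tab),
               rank_tab$pair[1])
  }

  invisible(list(cells = cells, registration = reg, composition = comp,
                 labels = labels, evaluation = evaluation, lr = lr,
                 rank = rank_tab, qc_report = qc$report,
                 out_dir = config$out_dir))
}
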