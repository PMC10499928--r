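#' Construct a spot frame
#'
#' Spot-based spatial transcriptomics captures transcripts in fixed-size
#' circular areas ("spots", 55 um diameter on Visium) laid out on a
#' hexagonal array.  A spot frame records each barcode's centre in
#' fixed-image pixels together with the physical scale.
#'
#' @param barcode unique spot barcodes
#' @param x,y spot centres in fixed-image pixels
#' @param diameter_um spot diameter in microns (default 55)
#' @param microns_per_pixel physical scale of the fixed image
#' @param in_tissue logical tissue flag per spot
#' @return a `spici_spots` data frame
#' @export
spot_frame <- function(barcode, x, y, diameter_um = 55,
                       microns_per_pixel = 1, in_tissue = TRUE) {
  barcode <- as.character(barcode)
  if (anyDuplicated(barcode)) stop("spot barcodes must be unique")
  stopifnot(diameter_um > 0, microns_per_pixel > 0)
  out <- data.frame(barcode = barcode, x = x, y = y,
                    in_tissue = rep_len(in_tissue, length(barcode)),
                    stringsAsFactors = FALSE)
  if (length(barcode) > 1L && length(barcode) <= 5000L) {
    dmin <- min(stats::dist(cbind(x, y))) * microns_per_pixel
    if (dmin < diameter_um)
      warning("spot discs overlap: minimum centre distance ", round(dmin, 2),
              " um < diameter ", diameter_um, " um")
  }
  attr(out, "diameter_um") <- diameter_um
  attr(out, "microns_per_pixel") <- microns_per_pixel
  class(out) <- c("spici_spots", "data.frame")
  out
}

#' Read spot positions
#'
#' Accepts the Visium-style 6-column CSV
#' (`barcode, in_tissue, array_row, array_col, pxl_row, pxl_col`, headerless
#' or with header) or a minimal 3-column `barcode, x, y` dialect.
#'
#' @param path CSV/TSV file
#' @inheritParams spot_frame
#' @return a `spici_spots` frame
#' @export
read_spot_positions <- function(path, diameter_um = 55, microns_per_pixel = 1) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) >= 6L) {
    if (!has_header)
      names(tab) <- c("barcode", "in_tissue", "array_row", "array_col",
                      "pxl_row", "pxl_col")
    spot_frame(tab$barcode, x = tab$pxl_col, y = tab$pxl_row,
               diameter_um = diameter_um,
               microns_per_pixel = microns_per_pixel,
               in_tissue = as.logical(tab$in_tissue))
  } else if (ncol(tab) >= 3L) {
    if (!has_header) names(tab) <- c("barcode", "x", "y")
    spot_frame(tab$barcode, tab$x, tab$y, diameter_um = diameter_um,
               microns_per_pixel = microns_per_pixel)
  } else stop("unrecognised spot-position table: need 3 or 6 columns")
}

#' Assign cells to spots
#'
#' A cell joins the spot whose centre lies within half the spot diameter
#' (27.5 um for the default d = 55 um) of the cell centroid.  Cells in the
#' gaps between spots stay unassigned: the capture areas do not tile the
#' section, and forcing nearest-spot assignment would attribute cells to
#' spots whose transcripts cannot contain them.  If several spots qualify
#' (impossible for non-overlapping grids, possible for user-supplied ones)
#' the nearest wins, ties broken by barcode order.
#'
#' @param cells annotated `spici_cells` with coordinates already in
#'   fixed-image pixels (see [transform_cells()])
#' @param spots a `spici_spots` frame
#' @param radius_um capture radius; default `diameter_um / 2`
#' @return character vector (one per cell) of barcodes, `NA` = unassigned
#' @export
assign_cells_to_spots <- function(cells, spots, radius_um = NULL) {
  if (nrow(spots) == 0L) stop("empty spot frame")
  mpp <- attr(spots, "microns_per_pixel")
  if (is.null(mpp) || !is.finite(mpp)) stop("missing microns_per_pixel scale")
  if (is.null(radius_um)) radius_um <- attr(spots, "diameter_um") / 2
  r_px <- radius_um / mpp
  ord <- order(spots$barcode)          # lexicographic tie-break
  sx <- spots$x[ord]; sy <- spots$y[ord]; sb <- spots$barcode[ord]
  out <- rep(NA_character_, nrow(cells))
  # chunked all-pairs distances; n and m are modest (10^3-10^4)
  chunk <- max(1L, floor(2e6 / length(sx)))
  for (start in seq(1L, nrow(cells), by = chunk)) {
    idx <- start:min(nrow(cells), start + chunk - 1L)
    d2 <- outer(cells$x[idx], sx, "-")^2 + outer(cells$y[idx], sy, "-")^2
    j <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_along(idx), j)]
    hit <- dmin <= r_px^2
    out[idx[hit]] <- sb[j[hit]]
  }
  out
}

#' Per-spot cell-type composition
#'
#' For spot \eqn{s}, the proportion of cell type \eqn{C} is
#' \eqn{P_s^C = N_C / N_s}, with \eqn{N_s} the number of cells falling in
#' the spot and \eqn{N_C} of them carrying label \eqn{C}.  Unassigned cells
#' are excluded and counted in the report; spots receiving no cell carry an
#' empty composition and are flagged.
#'
#' @param assignment character vector of barcodes per cell (`NA` =
#'   unassigned), as returned by [assign_cells_to_spots()]
#' @param annotations character vector of cell-type labels, same length
#' @param spots a `spici_spots` frame (defines the spot universe)
#' @return a `spici_composition`: long data frame
#'   `barcode, cell_type, count, proportion` with attributes `n_per_spot`
#'   (named `N_s` vector over all spots), `empty_spots`, `n_unassigned`
#' @export
compute_composition <- function(assignment, annotations, spots) {
  if (length(assignment) != length(annotations))
    stop("assignment and annotations differ in length")
  if (anyNA(annotations[!is.na(assignment)]))
    stop("annotation label missing for an assigned cell")
  ok <- !is.na(assignment)
  bad <- setdiff(assignment[ok], spots$barcode)
  if (length(bad)) stop("assigned barcode not in spot frame: ", bad[1L])
  tab <- table(factor(assignment[ok], levels = spots$barcode),
               annotations[ok])
  n_s <- rowSums(tab)
  long <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(long) <- c("barcode", "cell_type", "count")
  long <- long[long$count > 0L, , drop = FALSE]
  long <- long[order(match(long$barcode, spots$barcode), long$cell_type), ,
               drop = FALSE]
  rownames(long) <- NULL
  long$proportion <- long$count / n_s[long$barcode]
  attr(long, "n_per_spot") <- n_s
  attr(long, "empty_spots") <- names(n_s)[n_s == 0L]
  attr(long, "n_unassigned") <- sum(!ok)
  class(long) <- c("spici_composition", "data.frame")
  long
}

#' @export
print.spici_composition <- function(x, ...) {
  n_s <- attr(x, "n_per_spot")
  cat(sprintf(
    "Spot composition: %d spots (%d empty), %d cells assigned, %d unassigned\n",
    length(n_s), length(attr(x, "empty_spots")), sum(n_s),
    attr(x, "n_unassigned")))
  print(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("  ...", nrow(x) - 8L, "more rows\n")
  invisible(x)
}

#' Write a composition as long-format TSV
#'
#' @param composition a `spici_composition`
#' @param path output TSV
#' @export
write_composition <- function(composition, path) {
  utils::write.table(as.data.frame(composition), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dominant cell type per spot
#'
#' The spot's inferred label is the type with the highest proportion,
#' optionally after collapsing types into supergroups (e.g. all T/B/
#' macrophage types into `"Immune"` and tumor types into `"Tumor"` for a
#' tumor-versus-immune evaluation).  Ties go to the group occurring first in
#' `group_order` (default: sorted names); empty spots are labelled `NA`.
#'
#' @param composition a `spici_composition`
#' @param groups optional named character vector mapping cell type to
#'   supergroup; unmapped types keep their own name
#' @param group_order optional character vector fixing the tie-break order
#' @return named character vector, one label per spot (`NA` for empty spots)
#' @export
dominant_type <- function(composition, groups = NULL, group_order = NULL) {
  n_s <- attr(composition, "n_per_spot")
  lab <- composition$cell_type
  if (!is.null(groups)) {
    hit <- lab %in% names(groups)
    lab[hit] <- groups[lab[hit]]
  }
  if (is.null(group_order)) group_order <- sort(unique(lab))
  agg <- stats::aggregate(composition$proportion,
                          by = list(barcode = composition$barcode, group = lab),
                          FUN = sum)
  out <- rep(NA_character_, length(n_s))
  names(out) <- names(n_s)
  for (b in unique(agg$barcode)) {
    sub <- agg[agg$barcode == b, , drop = FALSE]
    sub <- sub[order(match(sub$group, group_order)), , drop = FALSE]
    out[b] <- sub$group[which.max(sub$x)]   # first max = earliest group
  }
  out
}

#' Compare inferred spot labels with reference annotations
#'
#' Accuracy and a truth x predicted confusion matrix over the barcodes
#' present on both sides; barcodes missing from either side (or labelled
#' `NA`) are excluded and counted.
#'
#' @param predicted named character vector of inferred labels
#' @param truth named character vector of reference labels
#' @return a `spici_evaluation`: list with `accuracy`, `confusion_matrix`,
#'   `per_class` (precision/recall), `n_spots_compared`, `n_excluded`
#' @export
evaluate_labels <- function(predicted, truth) {
  common <- intersect(names(predicted), names(truth))
  keep <- common[!is.na(predicted[common]) & !is.na(truth[common])]
  if (length(keep) == 0L) stop("no overlapping labelled spots to compare")
  p <- predicted[keep]; t_ <- truth[keep]
  classes <- sort(unique(c(p, t_)))
  cm <- table(factor(t_, classes), factor(p, classes))
  names(dimnames(cm)) <- c("truth", "predicted")
  acc <- sum(diag(cm)) / sum(cm)
  per_class <- data.frame(
    class = classes,
    precision = diag(cm) / pmax(colSums(cm), 1L),
    recall = diag(cm) / pmax(rowSums(cm), 1L),
    row.names = NULL
  )
  res <- list(accuracy = acc, confusion_matrix = cm, per_class = per_class,
              n_spots_compared = length(keep),
              n_excluded = length(union(names(predicted), names(truth))) -
                length(keep))
  class(res) <- "spici_evaluation"
  res
}

#' @export
print.spici_evaluation <- function(x, ...) {
  cat(sprintf("Spot-label evaluation on %d spots (%d excluded)\n",
              x$n_spots_compared, x$n_excluded))
  cat(sprintf("  accuracy: %.3f\n", x$accuracy))
  print(x$confusion_matrix)
  invisible(x)
}

#' Plot per-spot dominant labels
#'
#' Simple base-graphics map of spots coloured by label, for a quick visual
#' check of tumor/immune architecture.
#'
#' @param spots a `spici_spots` frame
#' @param labels named character vector of spot labels
#' @param ... passed to [graphics::plot()]
#' @export
plot_spot_labels <- function(spots, labels, ...) {
  lab <- labels[spots$barcode]
  lv <- sort(unique(stats::na.omit(lab)))
  col <- grDevices::hcl.colors(max(3L, length(lv)), "Dark 3")[match(lab, lv)]
  col[is.na(col)] <- "grey85"
  graphics::plot(spots$x, -spots$y, pch = 16, col = col, asp = 1,
                 xlab = "x (px)", ylab = "-y (px)", ...)
  graphics::legend("topright", legend = lv, bty = "n", pch = 16,
                   col = grDevices::hcl.colors(max(3L, length(lv)),
                                               "Dark 3")[seq_along(lv)])
  invisible(NULL)
}
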