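#' Construct a segmented-cell table
#'
#' The cell table is the tabular export of a segmentation run on a
#' multiplexed imaging section: one row per segmented cell with its centroid
#' (in pixels of the source image) and the mean intensity of every protein
#' marker.  A `transform_state` attribute tracks whether intensities are
#' `"raw"`, `"filtered"` (quantile-QC'd) or `"log"` (log1p-scaled).
#'
#' @param cell_id unique cell identifiers
#' @param x,y centroid coordinates in source-image pixels
#' @param intensities numeric matrix or data frame, one column per marker
#' @param microns_per_pixel physical scale of the source image
#' @param transform_state one of `"raw"`, `"filtered"`, `"log"`
#' @return a `spici_cells` data frame
#' @export
cell_table <- function(cell_id, x, y, intensities,
                       microns_per_pixel = NA_real_,
                       transform_state = "raw") {
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) stop("cell_id values must be unique")
  intensities <- as.data.frame(intensities, check.names = FALSE)
  names(intensities) <- .canon_marker(names(intensities))
  M <- as.matrix(intensities)
  if (!all(is.finite(M))) stop("intensities must be finite")
  if (any(M < 0)) stop("intensities must be non-negative")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("coordinates must be finite")
  out <- data.frame(cell_id = cell_id, x = x, y = y,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- cbind(out, intensities)
  attr(out, "transform_state") <- match.arg(transform_state,
                                            c("raw", "filtered", "log"))
  attr(out, "microns_per_pixel") <- microns_per_pixel
  class(out) <- c("spici_cells", "data.frame")
  out
}

#' @export
print.spici_cells <- function(x, ...) {
  cat(sprintf("Cell table: %d cells, %d markers [%s]\n",
              nrow(x), length(.cell_markers(x)), attr(x, "transform_state")))
  if ("cell_type" %in% names(x)) {
    tab <- sort(table(x$cell_type), decreasing = TRUE)
    cat("  annotated; top types:",
        paste(sprintf("%s (%d)", names(head(tab, 3L)), head(tab, 3L)),
              collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more cells\n")
  invisible(x)
}

#' Read / write a cell table
#'
#' CSV or TSV (by extension) with mandatory header `cell_id, x, y` followed
#' by one column per marker.  The Unicode marker spelling `"CD3ε"` is
#' accepted and canonicalised to `"CD3e"`.
#'
#' @param path file path (`.csv` or `.tsv`)
#' @param microns_per_pixel physical scale to record on the table
#' @param transform_state state of the stored intensities
#' @return a `spici_cells` table
#' @export
read_cell_table <- function(path, microns_per_pixel = NA_real_,
                            transform_state = "raw") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(tab)))
    stop("cell table needs columns: ", paste(need, collapse = ", "))
  extra <- intersect(c("cell_type", "score"), names(tab))
  markers <- setdiff(names(tab), c(need, extra))
  ct <- cell_table(tab$cell_id, tab$x, tab$y, tab[, markers, drop = FALSE],
                   microns_per_pixel = microns_per_pixel,
                   transform_state = transform_state)
  for (col in extra) ct[[col]] <- tab[[col]]
  ct
}

#' @rdname read_cell_table
#' @param cells a `spici_cells` table
#' @export
write_cell_table <- function(cells, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(cells), path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
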