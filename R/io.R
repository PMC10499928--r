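#' Write spot positions as a Visium-style CSV
#'
#' Columns `barcode, in_tissue, array_row, array_col, pxl_row, pxl_col`
#' (array indices are synthesised from rank when unknown).
#'
#' @param spots a `spici_spots` frame
#' @param path output CSV
#' @export
write_spot_positions <- function(spots, path) {
  out <- data.frame(
    barcode = spots$barcode,
    in_tissue = as.integer(spots$in_tissue),
    array_row = rank(spots$y, ties.method = "min"),
    array_col = rank(spots$x, ties.method = "min"),
    pxl_row = spots$y,
    pxl_col = spots$x
  )
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a spot x gene count matrix
#'
#' `read_counts()` accepts a dense TSV (rows = barcodes, first column
#' `barcode`) or an MTX file with `<stem>.barcodes.tsv` and
#' `<stem>.features.tsv` sidecars.  `write_counts_mtx()` writes the MTX
#' triplet for a matrix with dimnames.
#'
#' @param path TSV or MTX file
#' @return matrix with barcode rownames and gene colnames
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    M <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    rownames(M) <- readLines(paste0(stem, ".barcodes.tsv"))
    colnames(M) <- readLines(paste0(stem, ".features.tsv"))
    return(M)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  M <- as.matrix(tab[, -1, drop = FALSE])
  rownames(M) <- tab[[1]]
  M
}

#' @rdname read_counts
#' @param counts matrix with barcode rownames and gene colnames
#' @param stem output path stem; writes `<stem>.mtx`,
#'   `<stem>.barcodes.tsv`, `<stem>.features.tsv`
#' @export
write_counts_mtx <- function(counts, stem) {
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                  paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, ".barcodes.tsv"))
  writeLines(colnames(counts), paste0(stem, ".features.tsv"))
  invisible(paste0(stem, ".mtx"))
}

#' Write a QC or evaluation report as JSON
#'
#' @param report a named list of scalar counts/values (confusion matrices
#'   are flattened with their dimnames)
#' @param path output JSON
#' @export
write_report_json <- function(report, path) {
  if (inherits(report, "spici_evaluation"))
    report <- list(accuracy = report$accuracy,
                   n_spots_compared = report$n_spots_compared,
                   n_excluded = report$n_excluded,
                   confusion_matrix = as.data.frame(report$confusion_matrix))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
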