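#' Quantile filter on per-cell total intensity
#'
#' Computes each cell's total intensity over all markers and discards cells
#' whose total is strictly below the `lo` quantile or strictly above the
#' `hi` quantile of the total distribution (defaults 0.05 and 0.95).
#' Quantiles use the linear-interpolation (type-7) definition.  Kept cells
#' retain their input order.
#'
#' @param cells a raw `spici_cells` table
#' @param lo,hi quantile bounds, `0 <= lo < hi <= 1`
#' @return `list(cells, report)`: the filtered table (state `"filtered"`)
#'   and a QC report with counts and the quantile cutoffs
#' @export
filter_cells_quantile <- function(cells, lo = 0.05, hi = 0.95) {
  if (nrow(cells) == 0L) stop("empty cell table")
  if (!(lo >= 0 && hi <= 1 && lo < hi)) stop("need 0 <= lo < hi <= 1")
  if (!identical(attr(cells, "transform_state"), "raw"))
    stop("quantile filter runs on raw intensities")
  totals <- rowSums(as.matrix(cells[, .cell_markers(cells), drop = FALSE]))
  q <- stats::quantile(totals, c(lo, hi), type = 7, names = FALSE)
  low <- totals < q[1L]
  high <- totals > q[2L]
  keep <- !(low | high)
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "transform_state") <- "filtered"
  attr(out, "microns_per_pixel") <- attr(cells, "microns_per_pixel")
  class(out) <- class(cells)
  report <- list(
    n_input = nrow(cells),
    n_kept = sum(keep),
    n_removed_low = sum(low),
    n_removed_high = sum(high),
    q_low_value = q[1L],
    q_high_value = q[2L],
    lo = lo, hi = hi
  )
  stopifnot(report$n_input ==
              report$n_kept + report$n_removed_low + report$n_removed_high)
  list(cells = out, report = report)
}

#' Log-scale marker intensities
#'
#' Applies `log(1 + x)` elementwise so that zero intensities stay zero and
#' all scores downstream stay non-negative.  Refuses to transform twice.
#'
#' @param cells a raw or filtered `spici_cells` table
#' @return the table with state `"log"`
#' @export
log_transform <- function(cells) {
  state <- attr(cells, "transform_state")
  if (identical(state, "log")) stop("cell table is already log-scaled")
  markers <- .cell_markers(cells)
  M <- as.matrix(cells[, markers, drop = FALSE])
  if (any(M < 0)) stop("negative intensity")
  out <- cells
  for (m in markers) out[[m]] <- log1p(M[, m])
  attr(out, "transform_state") <- "log"
  out
}

#' Minimum-feature filter on spot counts
#'
#' Removes spots expressing fewer than `min_features` genes (a gene counts
#' as a feature of a spot when its count there is > 0).  Genes are never
#' removed.
#'
#' @param spot_counts spot x gene count matrix (dense or `Matrix` sparse),
#'   rows named by spot barcode
#' @param min_features minimum number of detected genes per spot
#'   (default 200, i.e. spots with <200 features are dropped)
#' @return `list(counts, report)` with the filtered matrix and counts
#' @export
filter_spots_min_features <- function(spot_counts, min_features = 200) {
  M <- spot_counts
  vals <- if (inherits(M, "sparseMatrix")) M@x else as.vector(as.matrix(M))
  if (any(vals < 0) || any(vals != floor(vals)))
    stop("counts must be non-negative integers")
  nfeat <- if (inherits(M, "sparseMatrix")) Matrix::rowSums(M > 0)
           else rowSums(as.matrix(M) > 0)
  keep <- nfeat >= min_features
  list(
    counts = M[keep, , drop = FALSE],
    report = list(n_input = nrow(M), n_kept = sum(keep),
                  n_removed = sum(!keep), min_features = min_features)
  )
}
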