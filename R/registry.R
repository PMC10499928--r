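# Canonical marker spelling: "CD3e" stands for CD3-epsilon everywhere in the
# package; the Unicode spelling is accepted on input and normalised here.
.canon_marker <- function(x) {
  x <- trimws(x)
  x[x == "CD3ε"] <- "CD3e"
  x
}

# Built-in panel: 17 cell types over 11 immune/cancer markers, in the order
# the panel defines them (order is the tie-break order for annotation).
# lineage: "tumor" or "immune"; is_subtype is FALSE only for the generic
# pan-leukocyte CD45 gate, which is a lineage gate rather than a subtype.
.builtin_panel17 <- function() {
  e <- list(
    list("Tumor",                    c("PANCK"),                          "tumor",  TRUE),
    list("Tumor infiltrating cells", c("CD45"),                           "immune", FALSE),
    list("Dividing tumor",           c("KI67", "PANCK"),                  "tumor",  TRUE),
    list("Dividing macrophage",      c("KI67", "CD68"),                   "immune", TRUE),
    list("Dividing CD8 T cells",     c("KI67", "CD45", "CD3e", "CD8"),    "immune", TRUE),
    list("Dividing CD4 T cells",     c("KI67", "CD45", "CD3e", "CD4"),    "immune", TRUE),
    list("Antigen-presenting cells", c("CD45", "HLA-DR"),                 "immune", TRUE),
    list("T-cell",                   c("CD45", "CD3e"),                   "immune", TRUE),
    list("B-cell",                   c("CD45", "CD20"),                   "immune", TRUE),
    list("Activated B cells",        c("CD45", "CD20", "HLA-DR"),         "immune", TRUE),
    list("CD8 T cells",              c("CD45", "CD3e", "CD8"),            "immune", TRUE),
    list("CD4 T cells",              c("CD45", "CD3e", "CD4"),            "immune", TRUE),
    list("Activated CD8 T cells",    c("CD45", "CD3e", "CD8", "CD107a"),  "immune", TRUE),
    list("Activated CD4 T cells",    c("CD45", "CD3e", "CD4", "CD107a"),  "immune", TRUE),
    list("Memory CD8 T cells",       c("CD45", "CD3e", "CD8", "CD45RO"),  "immune", TRUE),
    list("Memory CD4 T cells",       c("CD45", "CD3e", "CD4", "CD45RO"),  "immune", TRUE),
    list("Macrophage/monocyte",      c("CD45", "CD68"),                   "immune", TRUE)
  )
  new_registry(
    type_name = vapply(e, `[[`, "", 1L),
    markers   = lapply(e, `[[`, 2L),
    lineage   = vapply(e, `[[`, "", 3L),
    is_subtype = vapply(e, `[[`, TRUE, 4L)
  )
}

new_registry <- function(type_name, markers, lineage = NULL, is_subtype = NULL,
                         marker_universe = NULL) {
  if (anyDuplicated(type_name))
    stop("duplicate cell type names: ",
         paste(unique(type_name[duplicated(type_name)]), collapse = ", "))
  markers <- lapply(markers, .canon_marker)
  if (any(lengths(markers) == 0L))
    stop("every cell type needs a non-empty marker subset")
  universe <- if (is.null(marker_universe)) sort(unique(unlist(markers)))
              else .canon_marker(marker_universe)
  bad <- setdiff(unlist(markers), universe)
  if (length(bad))
    stop("marker(s) outside the declared universe: ", paste(bad, collapse = ", "))
  reg <- data.frame(type_name = type_name, stringsAsFactors = FALSE)
  reg$markers <- markers
  reg$lineage <- if (is.null(lineage)) rep(NA_character_, nrow(reg)) else lineage
  reg$is_subtype <- if (is.null(is_subtype)) rep(TRUE, nrow(reg)) else is_subtype
  attr(reg, "marker_universe") <- universe
  class(reg) <- c("spici_registry", "data.frame")
  reg
}

#' Load a cell-type registry
#'
#' A registry maps each cell type to the subset of protein markers that must
#' be jointly expressed for a cell to receive that label.  The built-in
#' `"paper17"` registry holds 17 tumor and immune cell types defined over 11
#' markers (PANCK, CD45, KI67, CD68, CD3e, CD8, CD4, HLA-DR, CD20, CD107a,
#' CD45RO); its entry order is the tie-break order used by
#' [annotate_cells()].
#'
#' @param source `"paper17"` for the built-in panel, or the path of a TSV
#'   with columns `type_name` and `markers` (markers `";"`-separated).
#' @return A `spici_registry`: a data frame with columns `type_name`,
#'   `markers` (list of character vectors), `lineage`, `is_subtype`, and a
#'   `marker_universe` attribute.
#' @examples
#' reg <- load_registry("paper17")
#' nrow(reg)                       # 17
#' length(marker_universe(reg))    # 11
#' @export
load_registry <- function(source = "paper17") {
  if (identical(source, "paper17")) return(.builtin_panel17())
  if (!file.exists(source)) stop("registry source not found: ", source)
  tab <- utils::read.delim(source, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("type_name", "markers")
  if (!all(need %in% names(tab)))
    stop("registry table needs columns: ", paste(need, collapse = ", "))
  mk <- ifelse(is.na(tab$markers), "", as.character(tab$markers))
  new_registry(
    type_name = tab$type_name,
    markers = strsplit(mk, ";", fixed = TRUE),
    lineage = if ("lineage" %in% names(tab)) tab$lineage else NULL,
    is_subtype = if ("is_subtype" %in% names(tab)) as.logical(tab$is_subtype) else NULL
  )
}

#' @rdname load_registry
#' @param registry a `spici_registry`
#' @export
marker_universe <- function(registry) attr(registry, "marker_universe")

#' Write a registry to TSV
#'
#' @param registry a `spici_registry`
#' @param path output file
#' @export
write_registry <- function(registry, path) {
  out <- data.frame(
    type_name = registry$type_name,
    markers = vapply(registry$markers, paste, "", collapse = ";"),
    lineage = registry$lineage,
    is_subtype = registry$is_subtype,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.spici_registry <- function(x, ...) {
  cat(sprintf("Cell-type registry: %d types over %d markers\n",
              nrow(x), length(marker_universe(x))))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-26s (%s)\n", x$type_name[i],
                paste(x$markers[[i]], collapse = ", ")))
  invisible(x)
}

#' Score one marker subset for one cell
#'
#' The typing score of subset \eqn{C} is the product of the cell's
#' intensities over the subset's markers, \eqn{\prod_{i \in C} x_i}
#' (`mode = "product"`), or its geometric mean
#' \eqn{(\prod_{i \in C} x_i)^{1/|C|}} (`mode = "geomean"`).  Any zero
#' intensity in the subset makes the score zero.
#'
#' @param intensities named numeric vector of non-negative marker intensities
#' @param subset character vector of marker names to score
#' @param mode `"product"` or `"geomean"`
#' @return a single non-negative score
#' @examples
#' score_subset(c(PANCK = 5, KI67 = 4), c("KI67", "PANCK"), "product")  # 20
#' score_subset(c(PANCK = 5, KI67 = 4), c("KI67", "PANCK"), "geomean")  # sqrt(20)
#' @export
score_subset <- function(intensities, subset, mode = c("product", "geomean")) {
  mode <- match.arg(mode)
  subset <- .canon_marker(subset)
  names(intensities) <- .canon_marker(names(intensities))
  missing <- setdiff(subset, names(intensities))
  if (length(missing))
    stop("marker(s) missing from intensities: ", paste(missing, collapse = ", "))
  x <- intensities[subset]
  if (any(x < 0)) stop("negative intensity")
  s <- prod(x)
  if (mode == "geomean") s <- s^(1 / length(subset))
  s
}

.cell_markers <- function(cells) {
  setdiff(names(cells), c("cell_id", "x", "y", "cell_type", "score"))
}

#' Annotate cells by marker-subset scoring
#'
#' Every registry entry is scored for every cell with [score_subset()] on the
#' log-scaled intensity matrix, and each cell is assigned the type with the
#' largest score.  Ties are broken by registry entry order (first entry
#' wins).  A cell whose best score does not exceed `min_score` is labelled
#' `"Unclassified"`.
#'
#' @param cells a cell table (see [cell_table()]) with
#'   `transform_state = "log"`
#' @param registry a `spici_registry`
#' @param mode `"product"` (the default scoring rule) or `"geomean"`;
#'   the two differ whenever candidate subsets have unequal sizes
#' @param min_score non-negative score threshold below or at which a cell is
#'   left `"Unclassified"` (default 0)
#' @return the cell table with `cell_type` and `score` columns appended
#' @export
annotate_cells <- function(cells, registry, mode = c("product", "geomean"),
                           min_score = 0) {
  mode <- match.arg(mode)
  stopifnot(min_score >= 0)
  if (!identical(attr(cells, "transform_state"), "log"))
    stop("annotate_cells expects log-scaled intensities; run log_transform() first")
  markers <- .cell_markers(cells)
  missing <- setdiff(unlist(registry$markers), markers)
  if (length(missing))
    stop("registry marker(s) absent from cell table: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(cells[, markers, drop = FALSE])
  if (any(X < 0)) stop("negative intensity in cell table")
  n <- nrow(X)
  scores <- matrix(0, n, nrow(registry))
  for (k in seq_len(nrow(registry))) {
    sub <- registry$markers[[k]]
    s <- X[, sub[1L]]
    for (m in sub[-1L]) s <- s * X[, m]
    if (mode == "geomean") s <- s^(1 / length(sub))
    scores[, k] <- s
  }
  best <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(n), best)]
  label <- registry$type_name[best]
  label[best_score <= min_score] <- "Unclassified"
  out <- cells
  out$cell_type <- label
  out$score <- best_score
  attr(out, "annotation_mode") <- mode
  class(out) <- unique(c("spici_cells", class(out)))
  out
}
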