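#' Spot neighbourhood graph
#'
#' Neighbourhoods feed the ligand-receptor score, which couples a spot's
#' expression with the mean expression of its surroundings.  In `"radius"`
#' mode a spot's neighbours are all spots within `param` microns (default
#' 1.5x the grid pitch captures the six hexagonal neighbours); in `"knn"`
#' mode its `param` nearest spots.  The spot itself is always included and
#' the graph is symmetric (knn is symmetrised by union).
#'
#' @param spots a `spici_spots` frame (needs `microns_per_pixel`)
#' @param mode `"radius"` or `"knn"`
#' @param param radius in microns, or k
#' @return named list: barcode -> character vector of neighbour barcodes
#' @export
build_neighbor_graph <- function(spots, mode = c("radius", "knn"),
                                 param = 150) {
  mode <- match.arg(mode)
  if (nrow(spots) < 2L) stop("need at least 2 spots for a neighbour graph")
  if (param <= 0) stop("param must be positive")
  mpp <- attr(spots, "microns_per_pixel")
  d_um <- as.matrix(stats::dist(cbind(spots$x, spots$y))) * mpp
  adj <- if (mode == "radius") d_um <= param
  else {
    k <- as.integer(param)
    A <- matrix(FALSE, nrow(spots), nrow(spots))
    for (i in seq_len(nrow(spots)))
      A[i, order(d_um[i, ])[seq_len(min(k + 1L, nrow(spots)))]] <- TRUE
    A | t(A)
  }
  diag(adj) <- TRUE
  out <- lapply(seq_len(nrow(spots)),
                function(i) spots$barcode[adj[i, ]])
  names(out) <- spots$barcode
  out
}

.neighbor_weight_matrix <- function(neighbors, barcodes) {
  n <- length(barcodes)
  i <- rep(seq_len(n), lengths(neighbors[barcodes]))
  j <- match(unlist(neighbors[barcodes], use.names = FALSE), barcodes)
  W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  W / Matrix::rowSums(W)
}

#' Ligand-receptor co-expression score per spot
#'
#' The score of pair (L, R) at spot \eqn{s} is the symmetric
#' spot-by-neighbourhood product
#' \deqn{score_s = \tfrac12 \{ L_s \cdot \bar R_{N(s)} + R_s \cdot \bar L_{N(s)} \}}
#' where \eqn{\bar g_{N(s)}} is the mean of gene \eqn{g} over the
#' neighbourhood of \eqn{s} (self included).  It is zero whenever either
#' gene is absent from the whole neighbourhood.
#'
#' @param expr spot x gene normalised expression matrix (rows named by
#'   barcode, columns by gene; non-negative)
#' @param pair list or data frame row with `ligand` and `receptor`
#' @param neighbors neighbour graph from [build_neighbor_graph()]
#' @return named numeric vector of per-spot scores
#' @export
lr_spot_scores <- function(expr, pair, neighbors) {
  for (g in c(pair$ligand, pair$receptor))
    if (!g %in% colnames(expr)) stop("gene missing from matrix: ", g)
  W <- .neighbor_weight_matrix(neighbors, rownames(expr))
  L <- expr[, pair$ligand]; R <- expr[, pair$receptor]
  s <- 0.5 * (L * as.vector(W %*% R) + R * as.vector(W %*% L))
  names(s) <- rownames(expr)
  s
}

#' Permutation p-values for ligand-receptor pairs
#'
#' Each tested pair's per-spot score is compared with the scores of
#' `n_background` random gene-gene pairs drawn uniformly from all genes of
#' the matrix, computed with the identical score.  The per-spot p-value is
#' \eqn{(1 + \#\{background \ge observed\}) / (1 + n_{background})}, never
#' exactly zero.  The background pool depends only on the matrix and the
#' seed -- not on which pairs are tested -- so subsetting the pair list
#' (e.g. to druggable pairs) leaves every retained pair's raw p-values
#' bit-identical.
#'
#' @param expr spot x gene normalised expression matrix
#' @param pairs data frame with columns `ligand`, `receptor` and optionally
#'   `druggable`, `annotation`
#' @param neighbors neighbour graph from [build_neighbor_graph()]
#' @param n_background number of random background pairs (>= 100;
#'   default 1000)
#' @param seed RNG seed controlling the background draw
#' @param alpha significance level applied to adjusted p-values
#' @param adjust_method `"bonferroni"` (default) or `"bh"`; see
#'   [adjust_pvalues()]
#' @return a `spici_lr` result: list with matrices `score`, `p`, `p_adj`,
#'   `significant` (spots x pairs), the `pairs` table, `alpha`, `n_background`
#' @export
permutation_pvalues <- function(expr, pairs, neighbors, n_background = 1000L,
                                seed = 1L, alpha = 0.05,
                                adjust_method = "bonferroni") {
  if (n_background < 100L) stop("n_background must be >= 100")
  genes <- colnames(expr)
  if (length(genes) < 20L) stop("too few genes to sample a background from")
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (any(pairs$ligand == pairs$receptor))
    stop("ligand and receptor must differ")
  W <- .neighbor_weight_matrix(neighbors, rownames(expr))
  M <- as.matrix(W %*% expr)          # neighbourhood means, all genes at once
  colnames(M) <- genes
  score_pair <- function(l, r) 0.5 * (expr[, l] * M[, r] + expr[, r] * M[, l])
  # background drawn before and independently of the tested pair list
  set.seed(seed)
  bg_l <- sample.int(length(genes), n_background, replace = TRUE)
  bg_r <- sample.int(length(genes) - 1L, n_background, replace = TRUE)
  bg_r <- ifelse(bg_r >= bg_l, bg_r + 1L, bg_r)   # uniform over l != r
  B <- 0.5 * (expr[, bg_l, drop = FALSE] * M[, bg_r, drop = FALSE] +
              expr[, bg_r, drop = FALSE] * M[, bg_l, drop = FALSE])
  pair_id <- paste(pairs$ligand, pairs$receptor, sep = "_")
  n_spot <- nrow(expr)
  score <- p <- matrix(NA_real_, n_spot, nrow(pairs),
                       dimnames = list(rownames(expr), pair_id))
  for (k in seq_len(nrow(pairs))) {
    obs <- score_pair(pairs$ligand[k], pairs$receptor[k])
    score[, k] <- obs
    p[, k] <- (1 + rowSums(B >= obs)) / (1 + n_background)
  }
  res <- list(score = score, p = p, pairs = pairs, alpha = alpha,
              n_background = n_background, seed = seed)
  class(res) <- "spici_lr"
  adjust_pvalues(res, method = adjust_method)
}

#' Multiple-testing adjustment of L-R p-values
#'
#' Adjusts each spot's p-values across the tested pairs.  The default,
#' Bonferroni, scales adjusted values proportionally with the number of
#' pairs tested (capped at 1), so subsetting the pair list relaxes
#' significance without touching raw p-values; Benjamini-Hochberg is also
#' offered.
#'
#' @param result a `spici_lr` result
#' @param method `"bonferroni"` or `"bh"`
#' @param alpha significance level; defaults to the result's
#' @return the result with `p_adj` and `significant` recomputed
#' @export
adjust_pvalues <- function(result, method = c("bonferroni", "bh"),
                           alpha = NULL) {
  method <- match.arg(method)
  if (is.null(alpha)) alpha <- result$alpha
  p <- result$p
  p_adj <- t(apply(p, 1L, stats::p.adjust,
                   method = if (method == "bh") "BH" else "bonferroni"))
  if (ncol(p) == 1L) p_adj <- matrix(p_adj, ncol = 1L)
  dimnames(p_adj) <- dimnames(p)
  result$p_adj <- p_adj
  result$alpha <- alpha
  result$adjust_method <- method
  result$significant <- p_adj < alpha
  result
}

#' @export
print.spici_lr <- function(x, ...) {
  cat(sprintf(
    "L-R permutation result: %d pairs x %d spots, %d background pairs\n",
    ncol(x$p), nrow(x$p), x$n_background))
  cat(sprintf("  adjustment: %s, alpha = %g; significant spot-pair calls: %d\n",
              x$adjust_method, x$alpha, sum(x$significant)))
  invisible(x)
}

#' Rank ligand-receptor pairs by significant-spot count
#'
#' Pairs are ranked descending by the number of spots where their adjusted
#' p-value clears `alpha`; ties are broken by the pair's best raw p-value,
#' then by name.  Optionally restricts to druggable pairs -- the retained
#' pairs' scores and raw p-values are untouched by the subsetting.
#'
#' @param result a `spici_lr` result
#' @param alpha significance level; defaults to the result's
#' @param druggable_only restrict the table to pairs flagged druggable
#' @return a `spici_ranktable` data frame: `pair, ligand, receptor,
#'   n_significant_spots, best_p, rank`
#' @export
rank_pairs <- function(result, alpha = NULL, druggable_only = FALSE) {
  if (!is.null(alpha) && alpha != result$alpha)
    result <- adjust_pvalues(result, result$adjust_method, alpha = alpha)
  keep <- seq_len(ncol(result$p))
  if (druggable_only) {
    if (is.null(result$pairs$druggable))
      stop("pairs table has no druggable flag")
    keep <- which(as.logical(result$pairs$druggable))
  }
  tab <- data.frame(
    pair = colnames(result$p)[keep],
    ligand = result$pairs$ligand[keep],
    receptor = result$pairs$receptor[keep],
    n_significant_spots = colSums(result$significant[, keep, drop = FALSE]),
    best_p = apply(result$p[, keep, drop = FALSE], 2L, min),
    stringsAsFactors = FALSE
  )
  ord <- order(-tab$n_significant_spots, tab$best_p, tab$pair)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("spici_ranktable", "data.frame")
  tab
}

#' Read a ligand-receptor pair list
#'
#' TSV with columns `ligand`, `receptor` and optionally `druggable` (0/1)
#' and `annotation` (drug name).
#'
#' @param path TSV file
#' @return data frame of pairs
#' @export
read_lr_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab)))
    stop("pair list needs columns ligand, receptor")
  if (!is.null(tab$druggable)) tab$druggable <- as.logical(tab$druggable)
  tab
}

#' Normalise a spot count matrix for L-R scoring
#'
#' Library-size normalisation to the median total count followed by
#' `log1p`, the conventional scale for co-expression scoring of spot counts.
#'
#' @param counts spot x gene count matrix
#' @return dense numeric matrix of normalised expression
#' @export
normalize_expression <- function(counts) {
  M <- as.matrix(counts)
  tot <- rowSums(M)
  tot[tot == 0] <- 1
  log1p(M / tot * stats::median(rowSums(M)))
}
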