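# Independent naive oracles and small fixture builders shared by the tests.

# brute-force cell typing: enumerate every (cell, type) pair, product or
# geometric-mean score, first-max tie break, best score <= min_score ->
# "Unclassified".  Deliberately written with plain loops, independent of the
# vectorised implementation.
oracle_annotate <- function(X, registry, mode = "product", min_score = 0) {
  labels <- character(nrow(X))
  for (j in seq_len(nrow(X))) {
    best <- -Inf; best_k <- NA_integer_
    for (k in seq_len(nrow(registry))) {
      sub <- registry$markers[[k]]
      s <- 1
      for (m in sub) s <- s * X[j, m]
      if (mode == "geomean") s <- s^(1 / length(sub))
      if (s > best) { best <- s; best_k <- k }
    }
    labels[j] <- if (best <= min_score) "Unclassified"
                 else registry$type_name[best_k]
  }
  labels
}

# random log-state cell table over the built-in 11-marker universe
random_cell_table <- function(n, seed, registry = load_registry("paper17")) {
  set.seed(seed)
  mk <- marker_universe(registry)
  X <- matrix(stats::runif(n * length(mk), 0, 3), n, length(mk),
              dimnames = list(NULL, mk))
  cell_table(seq_len(n), stats::runif(n), stats::runif(n), X,
             transform_state = "log")
}

# brute-force all-pairs spot assignment (radius + nearest + barcode order)
oracle_assign <- function(cells, spots, radius_um) {
  mpp <- attr(spots, "microns_per_pixel")
  out <- rep(NA_character_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    d <- sqrt((spots$x - cells$x[i])^2 + (spots$y - cells$y[i])^2) * mpp
    ok <- which(d <= radius_um)
    if (length(ok)) {
      ok <- ok[order(d[ok], spots$barcode[ok])]
      out[i] <- spots$barcode[ok[1L]]
    }
  }
  out
}

# minimal log-state table holding exactly the named intensities, rest 0
one_cell <- function(..., registry = load_registry("paper17")) {
  vals <- c(...)
  mk <- marker_universe(registry)
  X <- matrix(0, 1, length(mk), dimnames = list(NULL, mk))
  X[1, names(vals)] <- vals
  cell_table("c1", 0, 0, X, transform_state = "log")
}

tumor_immune_groups <- function(registry = load_registry("paper17")) {
  stats::setNames(ifelse(registry$lineage == "tumor", "Tumor", "Immune"),
                  registry$type_name)
}
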