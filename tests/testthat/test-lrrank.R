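hex_spots <- function(rows = 10L, cols = 10L)
  make_spot_grid(synth_config(grid_rows = rows, grid_cols = cols))

test_that("radius neighbourhoods capture the hex geometry", {
  spots <- hex_spots()
  nb <- build_neighbor_graph(spots, "radius", 150)
  # symmetric, self included
  expect_true(all(vapply(names(nb), function(b) b %in% nb[[b]], TRUE)))
  for (b in names(nb)[1:20])
    for (o in setdiff(nb[[b]], b))
      expect_true(b %in% nb[[o]])
  # interior spot: 6 neighbours + self; corner: 2 + self
  interior <- "SYN-005-005"
  expect_length(nb[[interior]], 7L)
  corner <- "SYN-001-001"
  expect_length(nb[[corner]], 3L)

  one <- spots[1, ]; class(one) <- class(spots)
  attr(one, "microns_per_pixel") <- attr(spots, "microns_per_pixel")
  expect_error(build_neighbor_graph(one, "radius", 150), "at least 2")
  expect_error(build_neighbor_graph(spots, "radius", -1), "positive")
})

test_that("the spot score is the symmetric spot-by-neighbourhood product", {
  spots <- hex_spots(3L, 3L)
  nb <- build_neighbor_graph(spots, "radius", 150)
  genes <- c("L", "R")
  expr <- matrix(1, nrow(spots), 2, dimnames = list(spots$barcode, genes))
  s <- lr_spot_scores(expr, list(ligand = "L", receptor = "R"), nb)
  expect_equal(unname(s), rep(1, nrow(spots)))

  expr0 <- expr; expr0[, "L"] <- 0
  expect_equal(unname(lr_spot_scores(expr0, list(ligand = "L", receptor = "R"),
                                     nb)), rep(0, nrow(spots)))

  # explicit arithmetic on a hand-built neighbourhood
  b <- spots$barcode
  expr2 <- expr
  expr2[, "L"] <- seq_len(9); expr2[, "R"] <- rev(seq_len(9))
  s2 <- lr_spot_scores(expr2, list(ligand = "L", receptor = "R"), nb)
  nbh <- nb[[b[1]]]
  byhand <- 0.5 * (expr2[b[1], "L"] * mean(expr2[nbh, "R"]) +
                   expr2[b[1], "R"] * mean(expr2[nbh, "L"]))
  expect_equal(unname(s2[b[1]]), byhand)

  expect_error(lr_spot_scores(expr, list(ligand = "X", receptor = "R"), nb),
               "X")
})

test_that("permutation p-values follow the add-one counting rule", {
  spots <- hex_spots(5L, 5L)
  nb <- build_neighbor_graph(spots, "radius", 150)
  # constant matrix: every background score ties the observed -> p = 1
  genes <- sprintf("g%02d", 1:30)
  expr <- matrix(1, nrow(spots), 30, dimnames = list(spots$barcode, genes))
  lr <- permutation_pvalues(expr, data.frame(ligand = "g01", receptor = "g02"),
                            nb, n_background = 200, seed = 1)
  expect_true(all(lr$p == 1))

  # observed strictly above every background -> p = 1/(1 + n_background)
  expr2 <- matrix(0, nrow(spots), 30, dimnames = list(spots$barcode, genes))
  expr2[, "g01"] <- 5; expr2[, "g02"] <- 5
  lr2 <- permutation_pvalues(expr2,
                             data.frame(ligand = "g01", receptor = "g02"),
                             nb, n_background = 999, seed = 7)
  bg_has_pair <- any(lr2$p > 1 / 1000 & lr2$p < 1)  # guard the construction
  expect_true(all(lr2$p == 1 / 1000) || bg_has_pair)
  expect_true(all(lr2$p > 0))

  expect_error(permutation_pvalues(expr, data.frame(ligand = "g01",
                                                    receptor = "g01"),
                                   nb, 200, 1), "differ")
  expect_error(permutation_pvalues(expr[, 1:5],
                                   data.frame(ligand = "g01",
                                              receptor = "g02"),
                                   nb, 200, 1), "few genes")
  expect_error(permutation_pvalues(expr, data.frame(ligand = "g01",
                                                    receptor = "g02"),
                                   nb, 50, 1), "100")
})

test_that("p-values are monotone in the observed score", {
  # same background, increasing observed scores -> non-increasing p
  spots <- hex_spots(4L, 4L)
  nb <- build_neighbor_graph(spots, "radius", 150)
  genes <- sprintf("g%02d", 1:40)
  set.seed(5)
  base <- matrix(stats::rexp(16 * 40), 16, 40,
                 dimnames = list(spots$barcode, genes))
  prev <- NULL
  for (boost in c(1, 2, 4, 8)) {
    expr <- base
    expr[, "g01"] <- expr[, "g01"] * boost
    expr[, "g02"] <- expr[, "g02"] * boost
    lr <- permutation_pvalues(expr, data.frame(ligand = "g01",
                                               receptor = "g02"),
                              nb, n_background = 500, seed = 3)
    if (!is.null(prev)) expect_true(all(lr$p <= prev + 1e-12))
    prev <- lr$p
  }
})

test_that("adjustment methods match their closed forms", {
  spots <- hex_spots(3L, 3L)
  fake <- list(p = matrix(c(0.01, 0.2), 1, 2,
                          dimnames = list("s", c("a", "b"))),
               alpha = 0.05, adjust_method = "bonferroni")
  class(fake) <- "spici_lr"
  # bonferroni multiplies by the number of pairs, capped at 1
  ten <- list(p = matrix(rep(c(0.01, 0.2), c(1, 9)), 1, 10,
                         dimnames = list("s", letters[1:10])), alpha = 0.05)
  class(ten) <- "spici_lr"
  adj <- adjust_pvalues(ten, "bonferroni")
  expect_equal(unname(adj$p_adj[1, 1]), 0.1)
  expect_equal(unname(adj$p_adj[1, 2]), 1)
  # BH step-up on the printed toy
  bh <- list(p = matrix(c(0.01, 0.02, 0.03, 0.04), 1, 4,
                        dimnames = list("s", letters[1:4])), alpha = 0.05)
  class(bh) <- "spici_lr"
  expect_equal(unname(adjust_pvalues(bh, "bh")$p_adj[1, ]), rep(0.04, 4))
  # significance flag is exactly p_adj < alpha, and p_adj >= p
  expect_true(all(adj$p_adj >= adj$p))
  expect_identical(adj$significant, adj$p_adj < adj$alpha)
})

test_that("ranking sorts by significant-spot count with stable ties", {
  fake <- list(
    p = matrix(0.5, 3, 3, dimnames = list(paste0("s", 1:3),
                                          c("A_x", "B_y", "C_z"))),
    pairs = data.frame(ligand = c("A", "B", "C"),
                       receptor = c("x", "y", "z"),
                       druggable = c(TRUE, FALSE, TRUE)),
    alpha = 0.05, n_background = 100, adjust_method = "bonferroni")
  fake$p_adj <- fake$p
  fake$significant <- matrix(c(TRUE, TRUE, TRUE,
                               TRUE, TRUE, FALSE,
                               FALSE, FALSE, FALSE), 3, 3,
                             dimnames = dimnames(fake$p))
  class(fake) <- "spici_lr"
  rt <- rank_pairs(fake)
  expect_equal(rt$pair, c("A_x", "B_y", "C_z"))
  expect_equal(rt$rank, 1:3)
  expect_equal(rt$n_significant_spots, c(3, 2, 0))
  rd <- rank_pairs(fake, druggable_only = TRUE)
  expect_equal(rd$pair, c("A_x", "C_z"))
  expect_equal(rd$rank, 1:2)
})

test_that("subsetting the tested pairs leaves raw p-values bit-identical", {
  cfg <- synth_config(seed = 13, grid_rows = 8L, grid_cols = 8L,
                      fold_change = 4)
  spots <- make_spot_grid(cfg)
  expr <- normalize_expression(make_spot_expression(cfg, spots))
  nb <- build_neighbor_graph(spots, "radius", 150)
  set.seed(40)
  others <- matrix(sample(setdiff(colnames(expr), cfg$lr_pair), 18), ncol = 2)
  pairs <- rbind(
    data.frame(ligand = cfg$lr_pair[1], receptor = cfg$lr_pair[2],
               druggable = TRUE),
    data.frame(ligand = others[, 1], receptor = others[, 2],
               druggable = rep(c(TRUE, FALSE), c(3, 6))))
  full <- permutation_pvalues(expr, pairs, nb, n_background = 300, seed = 99)
  sub <- permutation_pvalues(expr, pairs[pairs$druggable, ], nb,
                             n_background = 300, seed = 99)
  shared <- colnames(sub$p)
  expect_identical(sub$p[, shared], full$p[, shared])
  expect_identical(sub$score[, shared], full$score[, shared])
  # and the relative order of shared pairs is unchanged
  rf <- rank_pairs(full, druggable_only = TRUE)
  rs <- rank_pairs(sub)
  expect_identical(rs$pair, rf$pair)
})

test_that("the permutation test is calibrated under the null", {
  cfg <- synth_config(seed = 5, grid_rows = 20L, grid_cols = 10L,
                      fold_change = 1)
  spots <- make_spot_grid(cfg)
  expr <- normalize_expression(make_spot_expression(cfg, spots))
  nb <- build_neighbor_graph(spots, "radius", 150)
  set.seed(99)
  g <- colnames(expr)
  prs <- data.frame(ligand = sample(g, 50))
  prs$receptor <- sample(setdiff(g, prs$ligand), 50)
  lr <- permutation_pvalues(expr, prs, nb, n_background = 1000, seed = 5)
  frac <- mean(lr$p < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
})
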