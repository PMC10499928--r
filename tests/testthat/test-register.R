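test_that("image preparation grayscales, rotates and guards degenerate input", {
  rgb <- array(stats::runif(20 * 30 * 3), dim = c(20, 30, 3))
  mono <- matrix(stats::runif(20 * 30), 20, 30)
  prep <- prepare_images(mono, rgb)
  expect_true(is.matrix(prep$fixed))
  expect_equal(dim(prep$fixed), c(20L, 30L))
  expect_true(all(prep$fixed >= 0 & prep$fixed <= 1))

  # 90-degree pre-rotation swaps the moving image's dimensions
  cfg <- registration_config(initial_rotation = 90, downscale_factor = 1)
  p2 <- prepare_images(mono, mono, cfg)
  expect_equal(dim(p2$moving), c(30L, 20L))
  # and the recorded pre-transform maps content consistently:
  # a bright pixel must land where the forward map says it does
  img <- matrix(0, 20, 30); img[5, 25] <- 1
  p3 <- prepare_images(img, matrix(stats::runif(600), 20, 30), cfg)
  fwd <- spici:::affine_apply(attr(p3$moving, "pre"), cbind(25, 5))
  expect_equal(p3$moving[round(fwd[2]), round(fwd[1])], 1)

  expect_error(prepare_images(matrix(1, 5, 5), mono), "no structure")
})

test_that("mutual information matches its definition and is symmetric", {
  set.seed(2)
  a <- matrix(stats::runif(1e4), 100, 100)
  # MI of an image with itself is the entropy of its binned histogram
  bins <- 32L
  idx <- pmin(bins, 1L + floor((a - min(a)) / diff(range(a)) * bins))
  p <- tabulate(idx, bins) / length(a)
  expect_equal(mutual_information(a, a, bins), -sum(p[p > 0] * log(p[p > 0])),
               tolerance = 1e-12)

  # independent noise: MI -> 0 at large sample size
  b1 <- matrix(stats::runif(1e6), 1000, 1000)
  b2 <- matrix(stats::runif(1e6), 1000, 1000)
  expect_lt(mutual_information(b1, b2), 0.01)
  # shuffling pixels destroys all dependence
  shuf <- matrix(sample(a), nrow(a))
  expect_lt(mutual_information(a, shuf), 0.05)

  expect_equal(mutual_information(b1, b2), mutual_information(b2, b1),
               tolerance = 1e-9)
  expect_error(mutual_information(a, b1), "shape")
})

test_that("self-registration returns a near-identity transform", {
  cfg <- synth_config(seed = 4)
  img <- make_image_pair(cfg)$fixed
  res <- register_pair(img, img)
  expect_gte(res$mi_after, res$mi_before - 1e-6)
  expect_lt(max(abs(res$affine[, 1:2] - diag(2))), 0.01)
  expect_lt(max(abs(res$affine[, 3])), 0.5)
  expect_true(abs(det(res$affine[, 1:2])) > 0)
})

test_that("a pure translation is recovered within a pixel", {
  cfg <- synth_config(seed = 8, shift_px = c(10, -7))
  pair <- make_image_pair(cfg)
  res <- register_pair(pair$moving, pair$fixed)
  est <- transform_points(pair$landmarks_moving, res)
  err <- sqrt((est$x - pair$landmarks_fixed[, 1])^2 +
              (est$y - pair$landmarks_fixed[, 2])^2)
  expect_lt(mean(err), 1)
})

test_that("rotation plus scale is recovered to small landmark error", {
  cfg <- synth_config(seed = 9, rotation_deg = 8, scale = 1.05)
  pair <- make_image_pair(cfg)
  res <- register_pair(pair$moving, pair$fixed)
  est <- transform_points(pair$landmarks_moving, res)
  err <- sqrt((est$x - pair$landmarks_fixed[, 1])^2 +
              (est$y - pair$landmarks_fixed[, 2])^2)
  expect_lte(mean(err), 2)
})

test_that("point mapping applies the forward affine exactly", {
  id <- list(affine = spici:::affine_identity(),
             pre = spici:::affine_identity(), bspline = NULL,
             fixed_dim = c(100L, 100L), microns_per_pixel_fixed = 1)
  class(id) <- "spici_registration"
  pts <- cbind(c(1, 50.5, 99), c(2, 60.2, 98))
  expect_equal(as.matrix(transform_points(pts, id)[, 1:2]), pts,
               ignore_attr = TRUE)

  tr <- id; tr$affine <- cbind(diag(2), c(10, -7))
  out <- transform_points(pts, tr)
  expect_equal(out$x, pts[, 1] + 10)
  expect_equal(out$y, pts[, 2] - 7)
  expect_false(any(out$extrapolated))
})

test_that("mapped points round-trip through the generator's true inverse", {
  cfg <- synth_config(seed = 12, rotation_deg = -6, shift_px = c(-12, 5),
                      scale = 0.95)
  pair <- make_image_pair(cfg)
  res <- register_pair(pair$moving, pair$fixed)
  mapped <- transform_points(pair$landmarks_moving, res)
  back <- pair$inverse(as.matrix(mapped[, 1:2]))
  expect_lt(mean(sqrt(rowSums((back - pair$landmarks_moving)^2))), 1)
})

test_that("registration results survive JSON round-trips", {
  cfg <- synth_config(seed = 5, shift_px = c(4, 3))
  pair <- make_image_pair(cfg)
  res <- register_pair(pair$moving, pair$fixed,
                       registration_config(pyramid_levels = 2L,
                                           max_iters = 150L))
  tmp <- tempfile(fileext = ".json")
  write_registration(res, tmp)
  back <- read_registration(tmp)
  expect_equal(back$affine, res$affine)
  expect_equal(back$mi_after, res$mi_after)
  pts <- cbind(runif(5, 10, 200), runif(5, 10, 200))
  expect_equal(transform_points(pts, back), transform_points(pts, res))
})

test_that("deformable refinement keeps or improves MI and maps points back", {
  cfg <- synth_config(seed = 6, shift_px = c(6, -3), deform_amp_px = 2)
  pair <- make_image_pair(cfg)
  rcfg <- registration_config(stage = "affine_then_bspline",
                              bspline_grid_spacing = 64)
  res <- register_pair(pair$moving, pair$fixed, rcfg)
  expect_false(is.null(res$bspline))
  expect_gte(res$mi_after, res$mi_before - 1e-6)
  est <- transform_points(pair$landmarks_moving, res)
  err <- sqrt((est$x - pair$landmarks_fixed[, 1])^2 +
              (est$y - pair$landmarks_fixed[, 2])^2)
  expect_lte(mean(err), 3)
})
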