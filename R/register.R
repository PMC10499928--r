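#' Registration configuration
#'
#' Settings for aligning the nuclear-stain (moving) image onto the histology
#' (fixed) image.  The moving image may first be cropped, rotated and
#' downscaled so that its resolution and orientation roughly match the fixed
#' image; the optimiser then searches an affine (rotation, anisotropic
#' scale, shear, translation) maximising mutual information over a
#' multi-resolution pyramid, optionally followed by a spline-grid deformable
#' refinement.
#'
#' @param downscale_factor factor by which the moving image is shrunk before
#'   optimisation, or `NULL` to match the fixed image's size automatically
#' @param initial_rotation degrees of counter-clockwise pre-rotation applied
#'   to the moving image
#' @param initial_crop `c(x0, y0, width, height)` crop of the moving image,
#'   or `NULL`
#' @param mi_bins histogram bins for mutual information (default 32)
#' @param pyramid_levels number of resolution levels (default 3: 4x, 2x, 1x)
#' @param max_iters optimiser iterations per level (recycled)
#' @param convergence_tol relative MI tolerance for the optimiser
#' @param bspline_grid_spacing control-point spacing in fixed-image pixels
#' @param stage `"affine_only"` or `"affine_then_bspline"`
#' @param microns_per_pixel_fixed physical scale of the fixed image, carried
#'   onto transformed coordinates so downstream distances can use microns
#' @param seed retained for provenance; the optimiser is deterministic
#' @return a `spici_regconfig` list
#' @export
registration_config <- function(downscale_factor = NULL,
                                initial_rotation = 0,
                                initial_crop = NULL,
                                mi_bins = 32L,
                                pyramid_levels = 3L,
                                max_iters = c(500L, 400L, 400L),
                                convergence_tol = 1e-6,
                                bspline_grid_spacing = 64,
                                stage = c("affine_only", "affine_then_bspline"),
                                microns_per_pixel_fixed = NA_real_,
                                seed = 1L) {
  cfg <- list(downscale_factor = downscale_factor,
              initial_rotation = initial_rotation,
              initial_crop = initial_crop,
              mi_bins = as.integer(mi_bins),
              pyramid_levels = as.integer(pyramid_levels),
              max_iters = as.integer(max_iters),
              convergence_tol = convergence_tol,
              bspline_grid_spacing = bspline_grid_spacing,
              stage = match.arg(stage),
              microns_per_pixel_fixed = microns_per_pixel_fixed,
              seed = as.integer(seed))
  class(cfg) <- "spici_regconfig"
  cfg
}

#' Prepare an image pair for registration
#'
#' Both images are reduced to grayscale and rescaled to `[0, 1]`.  The
#' moving image is additionally cropped, rotated and downscaled per the
#' config so its capture area, orientation and resolution match the fixed
#' image.  The composite pre-transform (original moving pixel coordinates to
#' prepared coordinates) is recorded on the returned moving image so that
#' [transform_points()] can start from raw segmentation coordinates.
#'
#' @param moving nuclear-stain image (matrix or RGB array)
#' @param fixed histology image (matrix or RGB array)
#' @param config a [registration_config()]
#' @return `list(moving, fixed)` of grayscale matrices; the moving image
#'   carries attribute `"pre"` (a 2x3 forward affine)
#' @export
prepare_images <- function(moving, fixed, config = registration_config()) {
  if (length(moving) == 0L || length(fixed) == 0L) stop("empty image")
  mov <- rescale01(to_gray(moving))
  fix <- rescale01(to_gray(fixed))
  pre <- affine_identity()
  if (!is.null(config$initial_crop)) {
    cr <- config$initial_crop
    if (cr[3] < 1 || cr[4] < 1) stop("zero-size crop")
    xs <- seq(cr[1], min(ncol(mov), cr[1] + cr[3] - 1))
    ys <- seq(cr[2], min(nrow(mov), cr[2] + cr[4] - 1))
    mov <- mov[ys, xs, drop = FALSE]
    pre <- affine_compose(cbind(diag(2), c(1 - cr[1], 1 - cr[2])), pre)
  }
  if (config$initial_rotation %% 360 != 0) {
    mov <- rotate_image(mov, config$initial_rotation)
    pre <- affine_compose(attr(mov, "forward"), pre)
    attr(mov, "forward") <- NULL
  }
  f <- config$downscale_factor
  if (is.null(f)) f <- sqrt(prod(dim(mov)) / prod(dim(fix)))
  if (!isTRUE(all.equal(f, 1))) {
    if (f <= 0) stop("downscale_factor must be positive")
    oh <- max(2L, round(nrow(mov) / f)); ow <- max(2L, round(ncol(mov) / f))
    mov <- resize_bilinear(mov, oh, ow)
    # pixel centres: x_new = (x_old - 0.5) / f + 0.5
    pre <- affine_compose(cbind(diag(2) / f, c(0.5 - 0.5 / f, 0.5 - 0.5 / f)),
                          pre)
  }
  mov <- rescale01(mov)  # errors on a structureless (constant) image
  attr(mov, "pre") <- pre
  list(moving = mov, fixed = fix)
}

# resampling affine (fixed -> moving) from parameter vector
# p = (theta, log sx, log sy, shear, tx, ty), centred on the fixed image
.params_to_resample <- function(p, cf) {
  R <- matrix(c(cos(p[1]), sin(p[1]), -sin(p[1]), cos(p[1])), 2, 2)
  S <- diag(exp(p[2:3]))
  K <- matrix(c(1, 0, p[4], 1), 2, 2)
  M <- R %*% S %*% K
  cbind(M, cf + p[5:6] - M %*% cf)
}

#' Register a moving image onto a fixed image
#'
#' Maximises the mutual information between the fixed image and the
#' resampled moving image over a centred affine (rotation, anisotropic
#' scale, shear, translation), using a Gaussian-free block-mean pyramid and
#' Nelder-Mead search initialised at the centre-of-mass alignment of the two
#' images.  With `stage = "affine_then_bspline"` a first-order spline
#' control-point displacement grid is then optimised on top of the affine to
#' refine local alignment.
#'
#' The returned result stores the *forward point map* (moving to fixed
#' pixels); the internal fixed-to-moving resampling transform is inverted
#' before storage.
#'
#' @param moving,fixed prepared grayscale matrices (see [prepare_images()])
#' @param config a [registration_config()]
#' @return a `spici_registration` with elements `affine` (2x3 forward),
#'   `pre` (2x3 pre-transform), `bspline` (displacement grid or `NULL`),
#'   `mi_before`, `mi_after`, `converged`, `microns_per_pixel_fixed`
#' @export
register_pair <- function(moving, fixed, config = registration_config()) {
  pre <- attr(moving, "pre")
  if (is.null(pre)) pre <- affine_identity()
  bins <- config$mi_bins
  levels <- rev(2^(seq_len(config$pyramid_levels) - 1L))  # e.g. 4, 2, 1
  iters <- rep_len(config$max_iters, length(levels))
  com_shift <- center_of_mass(moving) - center_of_mass(fixed)
  p <- c(0, 0, 0, 0, com_shift)
  mi_before <- {
    cf <- c((ncol(fixed) + 1) / 2, (nrow(fixed) + 1) / 2)
    T0 <- .params_to_resample(p, cf)
    mutual_information(fixed, warp_affine(moving, T0, nrow(fixed), ncol(fixed)),
                       bins)
  }
  conv <- 0L
  for (li in seq_along(levels)) {
    s <- levels[li]
    fx <- if (s > 1) downscale_block(fixed, s) else fixed
    mv <- if (s > 1) downscale_block(moving, s) else moving
    cf <- c((ncol(fx) + 1) / 2, (nrow(fx) + 1) / 2)
    obj <- function(q) {
      qs <- q; qs[5:6] <- q[5:6] / s
      Tr <- .params_to_resample(qs, cf)
      -mutual_information(fx, warp_affine(mv, Tr, nrow(fx), ncol(fx)), bins)
    }
    fit <- stats::optim(p, obj, method = "Nelder-Mead",
                        control = list(maxit = iters[li],
                                       reltol = config$convergence_tol))
    p <- fit$par
    conv <- fit$convergence
  }
  cf <- c((ncol(fixed) + 1) / 2, (nrow(fixed) + 1) / 2)
  Tres <- .params_to_resample(p, cf)
  bspline <- NULL
  if (config$stage == "affine_then_bspline")
    bspline <- .fit_bspline(moving, fixed, Tres, config)
  warped <- .resample_full(moving, fixed, Tres, bspline)
  result <- list(
    affine = affine_invert(Tres),
    resample_affine = Tres,
    pre = pre,
    bspline = bspline,
    mi_before = mi_before,
    mi_after = mutual_information(fixed, warped, bins),
    converged = conv == 0L,
    fixed_dim = dim(fixed),
    microns_per_pixel_fixed = config$microns_per_pixel_fixed
  )
  class(result) <- "spici_registration"
  result
}

# first-order spline displacement grid on the fixed domain, resampling
# direction: T(xf) = Taff(xf) + D(xf)
.fit_bspline <- function(moving, fixed, Tres, config) {
  h <- nrow(fixed); w <- ncol(fixed)
  sp <- config$bspline_grid_spacing
  gx <- unique(c(seq(1, w, by = sp), w))
  gy <- unique(c(seq(1, h, by = sp), h))
  nx <- length(gx); ny <- length(gy)
  grid <- cbind(x = rep(seq_len(w), each = h), y = rep(seq_len(h), times = w))
  base <- affine_apply(Tres, grid)
  lambda <- 1e-4
  obj <- function(d) {
    D <- .bspline_disp(d, gx, gy, grid)
    img <- matrix(bilinear_sample(moving, base[, 1] + D[, 1],
                                  base[, 2] + D[, 2]), h, w)
    -mutual_information(fixed, img, config$mi_bins) + lambda * sum(d^2)
  }
  fit <- stats::optim(rep(0, 2 * nx * ny), obj, method = "L-BFGS-B",
                      lower = -sp / 2, upper = sp / 2,
                      control = list(maxit = 25L))
  list(grid_x = gx, grid_y = gy,
       dx = matrix(fit$par[seq_len(nx * ny)], ny, nx),
       dy = matrix(fit$par[nx * ny + seq_len(nx * ny)], ny, nx),
       spacing = sp)
}

# bilinear interpolation of control displacements at points (n x 2)
.bspline_disp <- function(d, gx, gy, pts) {
  nx <- length(gx); ny <- length(gy)
  dx <- matrix(d[seq_len(nx * ny)], ny, nx)
  dy <- matrix(d[nx * ny + seq_len(nx * ny)], ny, nx)
  ix <- findInterval(pts[, 1], gx, rightmost.closed = TRUE)
  iy <- findInterval(pts[, 2], gy, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), nx - 1L); iy <- pmin(pmax(iy, 1L), ny - 1L)
  fx <- (pts[, 1] - gx[ix]) / (gx[ix + 1L] - gx[ix])
  fy <- (pts[, 2] - gy[iy]) / (gy[iy + 1L] - gy[iy])
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  interp <- function(M) {
    M[cbind(iy, ix)] * (1 - fx) * (1 - fy) +
      M[cbind(iy, ix + 1L)] * fx * (1 - fy) +
      M[cbind(iy + 1L, ix)] * (1 - fx) * fy +
      M[cbind(iy + 1L, ix + 1L)] * fx * fy
  }
  cbind(interp(dx), interp(dy))
}

.resample_full <- function(moving, fixed, Tres, bspline) {
  h <- nrow(fixed); w <- ncol(fixed)
  if (is.null(bspline)) return(warp_affine(moving, Tres, h, w))
  grid <- cbind(x = rep(seq_len(w), each = h), y = rep(seq_len(h), times = w))
  base <- affine_apply(Tres, grid)
  D <- .bspline_disp(c(bspline$dx, bspline$dy), bspline$grid_x,
                     bspline$grid_y, grid)
  matrix(bilinear_sample(moving, base[, 1] + D[, 1], base[, 2] + D[, 2]), h, w)
}

#' @export
print.spici_registration <- function(x, ...) {
  cat("Image registration (moving -> fixed forward map)\n")
  cat(sprintf("  MI before: %.4f   MI after: %.4f   converged: %s\n",
              x$mi_before, x$mi_after, x$converged))
  cat("  affine:\n")
  print(round(x$affine, 4))
  if (!is.null(x$bspline))
    cat(sprintf("  deformable grid: %d x %d control points, spacing %g px\n",
                length(x$bspline$grid_y), length(x$bspline$grid_x),
                x$bspline$spacing))
  invisible(x)
}

#' Map points from moving-image to fixed-image coordinates
#'
#' Applies the full forward chain: the preparation pre-transform
#' (crop/rotate/downscale), then the forward affine, then -- when a
#' deformable stage was fitted -- the inverse of the deformable resampling
#' displacement (solved per point by fixed-point iteration).  Points whose
#' deformable solution leaves the fixed-image domain fall back to the affine
#' map alone and are flagged.
#'
#' @param points two-column matrix or data frame of `(x, y)` in original
#'   moving-image pixels
#' @param result a `spici_registration`
#' @return data frame `x`, `y` (fixed-image pixels), `extrapolated` flag
#' @export
transform_points <- function(points, result) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  storage.mode(pts) <- "double"
  pts <- affine_apply(result$pre, pts)
  fwd <- affine_apply(result$affine, pts)
  flag <- rep(FALSE, nrow(fwd))
  if (!is.null(result$bspline)) {
    bs <- result$bspline
    # solve Taff(xf) + D(xf) = xm  by  xf <- F(xm - D(xf)), F = affine inverse
    xf <- fwd
    for (it in seq_len(12L)) {
      D <- .bspline_disp(c(bs$dx, bs$dy), bs$grid_x, bs$grid_y, xf)
      xf_new <- affine_apply(result$affine, pts - D)
      if (max(abs(xf_new - xf)) < 1e-3) { xf <- xf_new; break }
      xf <- xf_new
    }
    h <- result$fixed_dim[1]; w <- result$fixed_dim[2]
    out_dom <- xf[, 1] < 1 | xf[, 1] > w | xf[, 2] < 1 | xf[, 2] > h
    flag <- out_dom
    fwd[!out_dom, ] <- xf[!out_dom, , drop = FALSE]
  }
  data.frame(x = fwd[, 1], y = fwd[, 2], extrapolated = flag)
}

#' Transform a cell table into fixed-image coordinates
#'
#' @param cells a `spici_cells` table with coordinates in original
#'   moving-image pixels
#' @param result a `spici_registration`
#' @return the table with `x`, `y` replaced by fixed-image coordinates and
#'   `microns_per_pixel` updated to the fixed image's scale
#' @export
transform_cells <- function(cells, result) {
  mapped <- transform_points(cells[, c("x", "y")], result)
  out <- cells
  out$x <- mapped$x
  out$y <- mapped$y
  attr(out, "microns_per_pixel") <- result$microns_per_pixel_fixed
  out
}

#' Serialize / read a registration result as JSON
#'
#' The affine and pre-transform are stored row-major; the displacement grid
#' as flat arrays plus shape and node positions.
#'
#' @param result a `spici_registration`
#' @param path JSON file path
#' @export
write_registration <- function(result, path) {
  obj <- list(
    affine = as.vector(t(result$affine)),
    resample_affine = as.vector(t(result$resample_affine)),
    pre = as.vector(t(result$pre)),
    mi_before = result$mi_before,
    mi_after = result$mi_after,
    converged = result$converged,
    fixed_dim = result$fixed_dim,
    microns_per_pixel_fixed = result$microns_per_pixel_fixed
  )
  if (!is.null(result$bspline))
    obj$bspline <- list(grid_x = result$bspline$grid_x,
                        grid_y = result$bspline$grid_y,
                        dx = as.vector(result$bspline$dx),
                        dy = as.vector(result$bspline$dy),
                        spacing = result$bspline$spacing)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_registration
#' @export
read_registration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  res <- list(
    affine = matrix(obj$affine, 2, 3, byrow = TRUE),
    resample_affine = matrix(obj$resample_affine, 2, 3, byrow = TRUE),
    pre = matrix(obj$pre, 2, 3, byrow = TRUE),
    bspline = NULL,
    mi_before = obj$mi_before,
    mi_after = obj$mi_after,
    converged = obj$converged,
    fixed_dim = obj$fixed_dim,
    microns_per_pixel_fixed = obj$microns_per_pixel_fixed
  )
  if (!is.null(obj$bspline)) {
    ny <- length(obj$bspline$grid_y); nx <- length(obj$bspline$grid_x)
    res$bspline <- list(grid_x = obj$bspline$grid_x,
                        grid_y = obj$bspline$grid_y,
                        dx = matrix(obj$bspline$dx, ny, nx),
                        dy = matrix(obj$bspline$dy, ny, nx),
                        spacing = obj$bspline$spacing)
  }
  class(res) <- "spici_registration"
  res
}
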