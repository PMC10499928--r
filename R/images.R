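# Images are numeric matrices: rows index y, columns index x, and the
# centre of pixel (row i, col j) sits at continuous coordinate (x = j, y = i).
# Affine point maps are 2x3 matrices A acting as A[,1:2] %*% c(x, y) + A[,3].

affine_identity <- function() cbind(diag(2), c(0, 0))

affine_apply <- function(A, pts) {
  pts <- as.matrix(pts)
  t(A[, 1:2] %*% t(pts[, 1:2, drop = FALSE]) + A[, 3])
}

affine_invert <- function(A) {
  L <- A[, 1:2]
  if (abs(det(L)) < .Machine$double.eps) stop("affine is singular")
  Li <- solve(L)
  cbind(Li, -Li %*% A[, 3])
}

# composition: (A %then% B)(p) = B(A(p))
affine_compose <- function(B, A) cbind(B[, 1:2] %*% A[, 1:2],
                                       B[, 1:2] %*% A[, 3] + B[, 3])

#' Read an image file as a numeric matrix or array
#'
#' PNG and TIFF are supported.  Multi-channel images come back as
#' height x width x channel arrays; single-channel as matrices.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`)
#' @return numeric matrix or array with values in `[0, 1]`
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  img
}

#' @rdname read_image
#' @param img numeric matrix or array in `[0, 1]`
#' @export
write_image <- function(img, path) {
  img[img < 0] <- 0; img[img > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3L && d[3] >= 3L)
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  if (length(d) == 3L) return(img[, , 1])
  stop("cannot interpret image with dims ", paste(d, collapse = "x"))
}

rescale01 <- function(img) {
  r <- range(img)
  if (r[2] - r[1] <= 0) stop("no structure to register: image is constant")
  (img - r[1]) / (r[2] - r[1])
}

# bilinear sampling at arbitrary continuous coordinates; outside -> 0
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- numeric(length(x))
  px <- function(xi, yi) {
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    v <- numeric(length(xi))
    v[ok] <- img[cbind(yi[ok], xi[ok])]
    v
  }
  out <- px(x0, y0) * (1 - fx) * (1 - fy) +
         px(x0 + 1, y0) * fx * (1 - fy) +
         px(x0, y0 + 1) * (1 - fx) * fy +
         px(x0 + 1, y0 + 1) * fx * fy
  out
}

# resample `img` onto an out_h x out_w canvas through map_fun:
# map_fun takes an n x 2 matrix of output (x, y) and returns source (x, y)
resample_image <- function(img, out_h, out_w, map_fun) {
  g <- cbind(x = rep(seq_len(out_w), each = out_h),
             y = rep(seq_len(out_h), times = out_w))
  src <- map_fun(g)
  matrix(bilinear_sample(img, src[, 1], src[, 2]), out_h, out_w)
}

warp_affine <- function(img, A_out2src, out_h = nrow(img), out_w = ncol(img)) {
  resample_image(img, out_h, out_w, function(p) affine_apply(A_out2src, p))
}

# integer-factor block-mean downscale (trims a remainder edge)
downscale_block <- function(img, f) {
  f <- as.integer(f)
  if (f <= 1L) return(img)
  h <- (nrow(img) %/% f) * f; w <- (ncol(img) %/% f) * f
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  a <- array(img, dim = c(f, h %/% f, f, w %/% f))
  apply(a, c(2L, 4L), mean)
}

resize_bilinear <- function(img, out_h, out_w) {
  sy <- nrow(img) / out_h; sx <- ncol(img) / out_w
  resample_image(img, out_h, out_w,
                 function(p) cbind((p[, 1] - 0.5) * sx + 0.5,
                                   (p[, 2] - 0.5) * sy + 0.5))
}

# rotate image content counter-clockwise by `deg`; canvas grows to the
# rotated bounding box; returns the image with the forward content map
# (old (x,y) -> new (x,y)) in attribute "forward"
rotate_image <- function(img, deg) {
  if (deg %% 360 == 0) { attr(img, "forward") <- affine_identity(); return(img) }
  h <- nrow(img); w <- ncol(img)
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)  # CCW in (x,y)
  if (deg %% 90 == 0) {
    k <- (deg %/% 90) %% 4
    out <- img
    for (i in seq_len(k))  # one CCW quarter turn in (x, y)
      out <- t(out[rev(seq_len(nrow(out))), , drop = FALSE])
    oh <- nrow(out); ow <- ncol(out)
  } else {
    corners <- cbind(c(1, w, 1, w), c(1, 1, h, h))
    rc <- t(R %*% t(sweep(corners, 2, c((w + 1) / 2, (h + 1) / 2))))
    ow <- ceiling(diff(range(rc[, 1]))) + 1L
    oh <- ceiling(diff(range(rc[, 2]))) + 1L
    cnew <- c((ow + 1) / 2, (oh + 1) / 2)
    cold <- c((w + 1) / 2, (h + 1) / 2)
    Ri <- solve(R)
    out <- resample_image(img, oh, ow,
                          function(p) sweep(t(Ri %*% t(sweep(p, 2, cnew))), 2,
                                            -cold))
  }
  cold <- c((w + 1) / 2, (h + 1) / 2)
  cnew <- c((ncol(out) + 1) / 2, (nrow(out) + 1) / 2)
  fwd <- cbind(R, cnew - R %*% cold)
  attr(out, "forward") <- fwd
  out
}

center_of_mass <- function(img) {
  tot <- sum(img)
  if (tot <= 0) return(c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2))
  c(sum(colSums(img) * seq_len(ncol(img))) / tot,
    sum(rowSums(img) * seq_len(nrow(img))) / tot)
}

#' Mutual information between two equally shaped images
#'
#' MI is computed from the joint intensity histogram with `bins` equal-width
#' bins per image (each binned over its own range):
#' \eqn{\sum_{a,b} p(a,b) \log\{p(a,b) / (p(a) p(b))\}}, in nats.
#' It is non-negative and symmetric, and is the similarity the registration
#' optimiser maximises -- it needs no intensity correspondence between the
#' two stain modalities.
#'
#' @param a,b numeric matrices of identical shape
#' @param bins number of histogram bins per image (default 32)
#' @return mutual information in nats
#' @export
mutual_information <- function(a, b, bins = 32L) {
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  bin_idx <- function(v) {
    r <- range(v)
    if (r[2] - r[1] <= 0) return(rep(1L, length(v)))
    pmin(bins, 1L + floor((v - r[1]) / (r[2] - r[1]) * bins))
  }
  ia <- bin_idx(as.vector(a)); ib <- bin_idx(as.vector(b))
  joint <- tabulate(ia + (ib - 1L) * bins, nbins = bins * bins) / length(ia)
  J <- matrix(joint, bins, bins)
  pa <- rowSums(J); pb <- colSums(J)
  nz <- J > 0
  sum(J[nz] * log(J[nz] / outer(pa, pb)[nz]))
}
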