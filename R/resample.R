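# Image resampling primitives: quarter-turn rotation, flips, separable
# bicubic/bilinear/nearest resize with antialiasing, and bilinear affine
# warping about the image center. Coordinates are (row, col), 1-based,
# with pixel centers at integer positions.

#' Rotate an image by quarter turns
#'
#' Counterclockwise rotation by `k` * 90 degrees (array operation, exact).
#'
#' @param img Numeric matrix.
#' @param k Integer number of quarter turns (mod 4).
#' @return Rotated matrix.
#' @export
rot90_image <- function(img, k = 1L) {
  k <- ((as.integer(k) %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) {
    img <- t(img)
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  }
  img
}

#' Flip an image
#'
#' @param img Numeric matrix.
#' @param axes Character subset of `c("vertical", "horizontal")`:
#'   `"vertical"` reverses rows (up-down flip), `"horizontal"` reverses
#'   columns (left-right flip).
#' @return Flipped matrix.
#' @export
flip_image <- function(img, axes = character()) {
  if ("vertical" %in% axes) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  if ("horizontal" %in% axes) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  img
}

# interpolation kernels
cubic_kernel <- function(x) {            # Keys cubic, a = -0.5
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax <= 2
  w[i1] <- 1.5 * ax[i1]^3 - 2.5 * ax[i1]^2 + 1
  w[i2] <- -0.5 * ax[i2]^3 + 2.5 * ax[i2]^2 - 4 * ax[i2] + 2
  w
}
linear_kernel <- function(x) pmax(0, 1 - abs(x))
nearest_kernel <- function(x) as.numeric(x >= -0.5 & x < 0.5)

# 1-D resampling weight matrix (n_out x n_in); when down-sampling with
# antialias the kernel is dilated by 1/scale (MATLAB imresize behaviour).
# Out-of-range taps are folded onto the nearest edge pixel (replicate
# padding) and rows renormalised to sum 1.
resize_weights <- function(n_in, n_out, kernel, support, antialias = TRUE) {
  scale <- n_out / n_in
  if (antialias && scale < 1) {
    kscale <- scale
    support <- support / scale
  } else kscale <- 1
  u <- (seq_len(n_out) - 0.5) / scale + 0.5        # centers in input coords
  left <- floor(u - support)
  width <- ceiling(2 * support) + 2L
  W <- matrix(0, n_out, n_in)
  for (t in 0:(width - 1L)) {
    j <- left + t
    w <- kernel((u - j) * kscale) * kscale
    jc <- pmin(pmax(j, 1L), n_in)                  # replicate edges
    W[cbind(seq_len(n_out), jc)] <- W[cbind(seq_len(n_out), jc)] + w
  }
  sw <- rowSums(W)
  sw[sw == 0] <- 1
  W / sw
}

#' Resize an image to a target shape
#'
#' Separable resampling with a bicubic (default), bilinear or nearest
#' kernel; antialiasing (kernel dilation) is applied when down-sampling.
#' The map is center-preserving: output pixel center `i` corresponds to
#' input coordinate `(i - 0.5) * n_in / n_out + 0.5`.
#'
#' @param img Numeric matrix.
#' @param target_shape Integer `(rows, cols)`.
#' @param interpolation `"bicubic"`, `"bilinear"` or `"nearest"`.
#' @param antialias Dilate the kernel when down-sampling.
#' @return Matrix of dimension `target_shape`.
#' @export
resize_image <- function(img, target_shape,
                         interpolation = c("bicubic", "bilinear", "nearest"),
                         antialias = TRUE) {
  interpolation <- match.arg(interpolation)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 2L || any(target_shape < 1L))
    stop("'target_shape' must be two positive integers")
  k <- switch(interpolation,
              bicubic = list(cubic_kernel, 2),
              bilinear = list(linear_kernel, 1),
              nearest = list(nearest_kernel, 0.5))
  Wr <- resize_weights(nrow(img), target_shape[1], k[[1]], k[[2]], antialias)
  Wc <- resize_weights(ncol(img), target_shape[2], k[[1]], k[[2]], antialias)
  Wr %*% img %*% t(Wc)
}

# Bilinear sampling of img at (row, col) coordinate vectors; points outside
# the image return `fill` and FALSE in the validity attribute.
bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  valid <- r >= 1 & r <= nr & c >= 1 & c <= nc
  r0 <- floor(r); c0 <- floor(c)
  r0 <- pmin(pmax(r0, 1L), nr - 1L); c0 <- pmin(pmax(c0, 1L), nc - 1L)
  fr <- r - r0; fc <- c - c0
  fr <- pmin(pmax(fr, 0), 1); fc <- pmin(pmax(fc, 0), 1)
  v00 <- img[cbind(r0, c0)];     v01 <- img[cbind(r0, c0 + 1L)]
  v10 <- img[cbind(r0 + 1L, c0)]; v11 <- img[cbind(r0 + 1L, c0 + 1L)]
  out <- (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
  out[!valid] <- fill
  attr(out, "valid") <- valid
  out
}

#' Warp an image by a 2-D affine transform
#'
#' Resamples `img` so that output pixel `x` (in coordinates centered on the
#' image center) takes the value of `img` at `A %*% x`: the affine maps
#' fixed (output) coordinates to moving (input) coordinates, the resampling
#' convention. Bilinear interpolation; out-of-view pixels take `fill` and
#' are flagged in the `"valid"` attribute.
#'
#' @param img Numeric matrix (the moving image).
#' @param affine 3x3 homogeneous matrix acting on `(row, col, 1)` vectors
#'   in center-origin coordinates.
#' @param out_shape Output shape; defaults to `dim(img)`.
#' @param fill Fill value outside the view.
#' @return Matrix with a logical `"valid"` attribute.
#' @export
warp_affine <- function(img, affine, out_shape = dim(img), fill = 0) {
  if (!all(dim(affine) == c(3L, 3L)) || abs(det(affine)) < 1e-12)
    stop("'affine' must be an invertible 3x3 matrix")
  nr <- out_shape[1]; nc <- out_shape[2]
  ctr_out <- (out_shape + 1) / 2
  ctr_in <- (dim(img) + 1) / 2
  rr <- rep(seq_len(nr), times = nc) - ctr_out[1]
  cc <- rep(seq_len(nc), each = nr) - ctr_out[2]
  src_r <- affine[1, 1] * rr + affine[1, 2] * cc + affine[1, 3] + ctr_in[1]
  src_c <- affine[2, 1] * rr + affine[2, 2] * cc + affine[2, 3] + ctr_in[2]
  v <- bilinear_sample(img, src_r, src_c, fill = fill)
  out <- matrix(v, nr, nc)
  attr(out, "valid") <- matrix(attr(v, "valid"), nr, nc)
  out
}
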