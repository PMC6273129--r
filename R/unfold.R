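#' Unfold a cube to a pixels x bands matrix
#'
#' Reshapes a cube into the (n_pixels x bands) matrix on which all
#' multivariate analysis operates. Pixels are ordered row-major: the row
#' index varies slowest, so pixel (r, c) of an R x C cube becomes matrix
#' row (r - 1) * C + c. An index map records the (row, col) of every matrix
#' row so that [refold()] can restore the spatial grid exactly.
#'
#' @param cube A [chem_cube()].
#' @param exclude_bad Drop bad pixels from the matrix (they are recorded as
#'   missing in the index map and restored as a fill value on refolding).
#' @return An object of class `unfolded`: `$values` (matrix),
#'   `$index_map` (n x 2 integer matrix of row, col), `$shape`, `$axis`,
#'   `$pixel_size_um`, `$modality`.
#' @export
unfold <- function(cube, exclude_bad = FALSE) {
  stopifnot(inherits(cube, "chem_cube"))
  d <- dim(cube$data)
  if (prod(d) == 0L) stop("empty cube")
  # aperm to (col, row, band); column-major flatten then orders col fastest
  m <- matrix(aperm(cube$data, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
  idx <- cbind(row = rep(seq_len(d[1]), each = d[2]),
               col = rep(seq_len(d[2]), times = d[1]))
  if (exclude_bad && any(cube$bad_pixel_mask)) {
    keep <- !cube$bad_pixel_mask[idx]
    m <- m[keep, , drop = FALSE]
    idx <- idx[keep, , drop = FALSE]
  }
  structure(list(values = m, index_map = idx, shape = d[1:2],
                 axis = cube$axis, pixel_size_um = cube$pixel_size_um,
                 modality = cube$modality),
            class = "unfolded")
}

#' Refold an unfolded matrix back into a cube
#'
#' Inverse of [unfold()] on the included pixels; pixels that were excluded
#' (e.g. bad pixels) are filled with `fill` and flagged in the bad-pixel
#' mask of the result.
#'
#' @param um An `unfolded` object (its `$values` may have been replaced by
#'   any matrix with the same number of rows).
#' @param fill Value placed at excluded pixels.
#' @param axis Optional replacement [spectral_axis()] when the band
#'   dimension changed (e.g. after derivative trimming or prediction).
#' @return A [chem_cube()].
#' @export
refold <- function(um, fill = NA_real_, axis = NULL) {
  stopifnot(inherits(um, "unfolded"))
  m <- um$values
  if (nrow(m) != nrow(um$index_map))
    stop("matrix rows and index map are inconsistent")
  if (any(um$index_map[, 1] > um$shape[1]) || any(um$index_map[, 2] > um$shape[2]))
    stop("index map exceeds target shape")
  if (is.null(axis)) axis <- um$axis
  if (length(axis$values) != ncol(m))
    stop("axis length does not match matrix columns")
  nb <- ncol(m)
  arr <- array(fill, dim = c(um$shape, nb))
  excl <- matrix(TRUE, um$shape[1], um$shape[2])
  excl[um$index_map] <- FALSE
  for (b in seq_len(nb)) {
    slice <- matrix(fill, um$shape[1], um$shape[2])
    slice[um$index_map] <- m[, b]
    arr[, , b] <- slice
  }
  # excluded pixels (fill may be non-finite) are covered by the mask,
  # so chem_cube()'s finiteness check still applies to real data
  chem_cube(arr, axis, pixel_size_um = um$pixel_size_um,
            bad_pixel_mask = excl, modality = um$modality)
}
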