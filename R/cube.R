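#' Chemical image cube
#'
#' The central container of the package: a 3-D array (rows x cols x bands)
#' where each spatial pixel holds a full spectrum, together with its
#' [spectral_axis()], the physical pixel size and a bad-pixel mask.
#'
#' @param data Numeric 3-D array, rows x cols x bands.
#' @param axis A [spectral_axis()]; its length must equal `dim(data)[3]`.
#' @param pixel_size_um Positive pixel size(s) in micrometres; length 1
#'   (square pixels) or 2 (row, col).
#' @param bad_pixel_mask Logical rows x cols matrix; `TRUE` marks a bad
#'   pixel. Defaults to all-`FALSE`.
#' @param modality Modality label; defaults to the axis label.
#' @return An object of class `chem_cube`.
#' @export
chem_cube <- function(data, axis, pixel_size_um = 1,
                      bad_pixel_mask = NULL, modality = axis$modality) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a rows x cols x bands array")
  d <- dim(data)
  if (d[1] < 1L || d[2] < 1L) stop("cube has no pixels")
  if (length(axis$values) != d[3])
    stop(sprintf("axis has %d bands but data has %d", length(axis$values), d[3]))
  if (any(pixel_size_um <= 0) || !length(pixel_size_um) %in% 1:2)
    stop("'pixel_size_um' must be 1 or 2 positive values")
  if (length(pixel_size_um) == 1L) pixel_size_um <- rep(pixel_size_um, 2L)
  if (is.null(bad_pixel_mask)) {
    bad_pixel_mask <- matrix(FALSE, d[1], d[2])
  } else {
    if (!is.logical(bad_pixel_mask) || !all(dim(bad_pixel_mask) == d[1:2]))
      stop("'bad_pixel_mask' must be a logical rows x cols matrix")
  }
  ok <- rep(!bad_pixel_mask, times = d[3])
  if (!all(is.finite(data[ok])))
    stop("cube contains non-finite values outside the bad-pixel mask")
  structure(list(data = data, axis = axis,
                 pixel_size_um = as.numeric(pixel_size_um),
                 bad_pixel_mask = bad_pixel_mask,
                 modality = modality),
            class = "chem_cube")
}

#' @export
dim.chem_cube <- function(x) dim(x$data)

#' @export
print.chem_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<chem_cube> %s: %d x %d pixels (%g x %g um), %d bands [%s], %d bad pixels\n",
              if (nzchar(x$modality)) x$modality else "(unlabelled)",
              d[1], d[2], x$pixel_size_um[1], x$pixel_size_um[2],
              d[3], x$axis$unit, sum(x$bad_pixel_mask)))
  invisible(x)
}

#' Extract a single band image from a cube
#'
#' @param cube A [chem_cube()].
#' @param band Band position on the spectral axis (nearest-band lookup,
#'   tolerance half the local band spacing) or, with `index = TRUE`, a band
#'   index.
#' @param index Interpret `band` as an integer index.
#' @return A numeric rows x cols matrix.
#' @export
band_image <- function(cube, band, index = FALSE) {
  b <- if (index) as.integer(band) else nearest_band(cube$axis, band)
  if (b < 1L || b > dim(cube$data)[3]) stop("band index out of range")
  cube$data[, , b]
}

# nearest-band lookup with tolerance = half the local band spacing
nearest_band <- function(axis, value) {
  v <- axis$values
  i <- which.min(abs(v - value))
  sp <- if (length(v) > 1L) {
    local <- abs(diff(v))
    if (i == 1L) local[1] else if (i == length(v)) local[length(local)] else
      max(local[i - 1L], local[i])
  } else Inf
  if (abs(v[i] - value) > sp / 2 + 1e-9)
    stop(sprintf("no band within tolerance of %g (nearest is %g)", value, v[i]))
  i
}
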