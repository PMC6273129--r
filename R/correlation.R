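# Inter-modality spectral correlation maps over registered pixels.

#' Pearson correlation map between the bands of two modalities
#'
#' Entry (i, j) is the Pearson correlation over registered pixels between
#' band i of the first modality and band j of the second. Zero-variance
#' bands yield `NA` entries with a warning.
#'
#' @param a,b [unfold()]ed matrices over the same pixels.
#' @return A `corr_map`: `$r` (bands_a x bands_b), `$axis_a`, `$axis_b`.
#' @export
correlation_map <- function(a, b) {
  stopifnot(inherits(a, "unfolded"), inherits(b, "unfolded"))
  if (nrow(a$values) != nrow(b$values)) stop("pixel counts differ")
  if (nrow(a$values) < 3L) stop("need at least 3 pixels")
  zva <- apply(a$values, 2L, stats::sd) == 0
  zvb <- apply(b$values, 2L, stats::sd) == 0
  if (any(zva) || any(zvb))
    warning("zero-variance band(s): correlations reported as NA")
  r <- suppressWarnings(stats::cor(a$values, b$values))
  structure(list(r = r, axis_a = a$axis, axis_b = b$axis),
            class = "corr_map")
}

#' @export
print.corr_map <- function(x, ...) {
  cat(sprintf("<corr_map> %d x %d bands (%s x %s), max |r| = %.3f\n",
              nrow(x$r), ncol(x$r), x$axis_a$modality, x$axis_b$modality,
              max(abs(x$r), na.rm = TRUE)))
  invisible(x)
}

# collapse sorted band values into "lo-hi" range strings over contiguous
# axis index runs
band_runs <- function(axis, idx) {
  idx <- sort(unique(idx))
  if (!length(idx)) return(character(0))
  breaks <- c(0L, which(diff(idx) != 1L), length(idx))
  vapply(seq_len(length(breaks) - 1L), function(i) {
    run <- idx[(breaks[i] + 1L):breaks[i + 1L]]
    lo <- axis$values[run[1]]; hi <- axis$values[run[length(run)]]
    if (lo == hi) sprintf("%.6g", lo) else sprintf("%.6g-%.6g", lo, hi)
  }, character(1))
}

#' Band pairs with correlation above a threshold
#'
#' Returns all band pairs with `|r| > threshold`, sorted by decreasing
#' `|r|`, plus the contiguous band ranges involved per modality (the form
#' in which highly correlated regions are usually reported).
#'
#' @param map A [correlation_map()].
#' @param threshold Cut in `(0, 1]` (default 0.85).
#' @return Data frame with `band_a`, `band_b`, `r`; attributes `ranges_a`
#'   and `ranges_b` hold the contiguous range strings. Empty when nothing
#'   exceeds the threshold.
#' @export
high_correlation_pairs <- function(map, threshold = 0.85) {
  stopifnot(inherits(map, "corr_map"))
  if (threshold <= 0 || threshold > 1) stop("'threshold' must be in (0, 1]")
  hit <- which(abs(map$r) > threshold, arr.ind = TRUE)
  out <- data.frame(band_a = map$axis_a$values[hit[, 1]],
                    band_b = map$axis_b$values[hit[, 2]],
                    r = map$r[hit])
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ranges_a") <- band_runs(map$axis_a, hit[, 1])
  attr(out, "ranges_b") <- band_runs(map$axis_b, hit[, 2])
  out
}

#' Slice a correlation map at one band of the first modality
#'
#' The requested row of the map (correlation between one band of modality
#' A and every band of modality B), with nearest-band lookup at half the
#' local band spacing.
#'
#' @param map A [correlation_map()].
#' @param band_of_a Band position on the first modality's axis.
#' @return Numeric vector over the second modality's bands, with the
#'   resolved band position as attribute `"band"`.
#' @export
correlation_slice <- function(map, band_of_a) {
  stopifnot(inherits(map, "corr_map"))
  i <- nearest_band(map$axis_a, band_of_a)
  structure(map$r[i, ], band = map$axis_a$values[i],
            names = sprintf("%.6g", map$axis_b$values))
}

#' Write a correlation map as a CSV matrix
#'
#' @param map A [correlation_map()].
#' @param path CSV path; rows = first modality's bands.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(map, path) {
  df <- as.data.frame(map$r)
  names(df) <- sprintf("%.6g", map$axis_b$values)
  df <- cbind(band_a = map$axis_a$values, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
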