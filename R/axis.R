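#' Spectral axis of a chemical image cube
#'
#' Describes the spectral dimension of a cube: the ordered band positions
#' (wavenumbers in cm^-1, Raman shifts in cm^-1, or wavelengths in nm),
#' the unit and a free-text modality label (e.g. `"IR"`, `"Raman"`).
#'
#' @param values Numeric vector of band positions; must be strictly
#'   monotonic and of length >= 2.
#' @param unit One of `"wavenumber"`, `"raman_shift"`, `"wavelength"`.
#' @param modality Free-text modality label.
#' @return An object of class `spectral_axis`.
#' @export
spectral_axis <- function(values,
                          unit = c("wavenumber", "raman_shift", "wavelength"),
                          modality = "") {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a spectral axis needs at least 2 bands")
  d <- diff(values)
  if (!all(is.finite(values)) || !(all(d > 0) || all(d < 0)))
    stop("spectral axis values must be finite and strictly monotonic")
  structure(list(values = values, unit = unit, modality = modality),
            class = "spectral_axis")
}

#' @export
length.spectral_axis <- function(x) length(x$values)

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %s [%s], %d bands, %g .. %g\n",
              if (nzchar(x$modality)) x$modality else "(unlabelled)",
              x$unit, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Composite axis for fused cubes
#'
#' Fused cubes (low-level concatenation, mid-level PC-score stacks) have no
#' physically monotonic spectral axis; the band positions are replaced by a
#' channel index 1..B and each channel carries a bookkeeping record of its
#' origin (modality, original band value or PC index).
#'
#' @param bands A data.frame with one row per channel; must contain a
#'   `modality` column. Typical extra columns: `value` (original band
#'   position) or `pc` and `var_pct`.
#' @param unit Unit tag carried for display only.
#' @return A `spectral_axis` with additional class `fused_axis`; `$bands`
#'   holds the per-channel table.
#' @export
fused_axis <- function(bands, unit = "wavenumber") {
  stopifnot(is.data.frame(bands), nrow(bands) >= 1L, "modality" %in% names(bands))
  ax <- structure(list(values = as.numeric(seq_len(nrow(bands))),
                       unit = unit,
                       modality = paste(unique(bands$modality), collapse = "+"),
                       bands = bands),
                  class = c("fused_axis", "spectral_axis"))
  ax
}

# subset an axis to a band index set, preserving fused bookkeeping
axis_subset <- function(axis, idx) {
  out <- axis
  out$values <- axis$values[idx]
  if (!is.null(axis$bands)) out$bands <- axis$bands[idx, , drop = FALSE]
  out
}
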