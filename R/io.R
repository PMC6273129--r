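#' Write a cube as an ENVI-style header + binary pair
#'
#' Writes a text `.hdr` header (samples/lines/bands, interleave, data type,
#' wavelength list, plus pixel-size and modality metadata) and a raw
#' little-endian binary file. Doubles (`data type 5`, the default) round-trip
#' bit-exactly.
#'
#' @param cube A [chem_cube()].
#' @param path Path of the binary file; the header is written to
#'   `paste0(path, ".hdr")`.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @param data_type ENVI data type code: 4 (float32) or 5 (float64).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip"),
                       data_type = 5L) {
  stopifnot(inherits(cube, "chem_cube"))
  interleave <- match.arg(interleave)
  if (!data_type %in% c(4L, 5L)) stop("supported data types: 4 (float32), 5 (float64)")
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {chemfuse chemical image cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength units = %s", cube$axis$unit),
    sprintf("pixel size = {%.10g, %.10g}", cube$pixel_size_um[1], cube$pixel_size_um[2]),
    sprintf("modality = %s", cube$modality),
    sprintf("wavelength = {%s}", paste(sprintf("%.10g", cube$axis$values), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  arr <- cube$data
  vec <- switch(interleave,
    # bsq: sample fastest, then line, then band
    bsq = as.vector(aperm(arr, c(2L, 1L, 3L))),
    # bil: sample fastest, then band, then line
    bil = as.vector(aperm(arr, c(2L, 3L, 1L))),
    # bip: band fastest, then sample, then line
    bip = as.vector(aperm(arr, c(3L, 2L, 1L))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(vec), con, size = if (data_type == 5L) 8L else 4L,
           endian = "little")
  invisible(path)
}

#' Read an ENVI-style cube written by [write_envi()]
#'
#' Parses the text header (including multi-line `{ }` values) and reads the
#' binary data for BSQ, BIL or BIP interleaves.
#'
#' @param path Path of the binary file (header expected at
#'   `paste0(path, ".hdr")`, falling back to replacing the extension).
#' @return A [chem_cube()].
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) hdr_path <- sub("\\.[^.]*$", ".hdr", path)
  if (!file.exists(hdr_path)) stop("ENVI header not found for ", path)
  fields <- parse_envi_header(readLines(hdr_path, warn = FALSE))
  need <- c("samples", "lines", "bands", "data type", "interleave")
  if (!all(need %in% names(fields)))
    stop("ENVI header is missing required fields")
  ns <- as.integer(fields[["samples"]]); nl <- as.integer(fields[["lines"]])
  nb <- as.integer(fields[["bands"]]); dt <- as.integer(fields[["data type"]])
  il <- tolower(fields[["interleave"]])
  if (!dt %in% c(4L, 5L)) stop("unsupported ENVI data type: ", dt)
  con <- file(path, "rb")
  on.exit(close(con))
  vec <- readBin(con, "numeric", n = ns * nl * nb,
                 size = if (dt == 5L) 8L else 4L, endian = "little")
  if (length(vec) != ns * nl * nb) stop("ENVI binary is truncated")
  arr <- switch(il,
    bsq = aperm(array(vec, c(ns, nl, nb)), c(2L, 1L, 3L)),
    bil = aperm(array(vec, c(ns, nb, nl)), c(3L, 1L, 2L)),
    bip = aperm(array(vec, c(nb, ns, nl)), c(3L, 2L, 1L)),
    stop("unsupported interleave: ", il))
  wl <- if ("wavelength" %in% names(fields)) {
    as.numeric(strsplit(fields[["wavelength"]], ",")[[1]])
  } else seq_len(nb)
  unit <- if ("wavelength units" %in% names(fields) &&
              fields[["wavelength units"]] %in%
                c("wavenumber", "raman_shift", "wavelength"))
    fields[["wavelength units"]] else "wavenumber"
  px <- if ("pixel size" %in% names(fields))
    as.numeric(strsplit(fields[["pixel size"]], ",")[[1]]) else c(1, 1)
  modality <- if ("modality" %in% names(fields)) fields[["modality"]] else ""
  chem_cube(arr, spectral_axis(wl, unit, modality), pixel_size_um = px,
            modality = modality)
}

parse_envi_header <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  txt <- sub("^ENVI\\s*\n", "", txt)
  # collapse newlines inside { ... } blocks so each field is one line
  txt <- gsub("\\{([^}]*)\\}", "{\\1}", txt)
  repeat {
    new <- sub("(\\{[^}]*)\n", "\\1 ", txt)
    if (identical(new, txt)) break
    txt <- new
  }
  fields <- list()
  for (ln in strsplit(txt, "\n")[[1]]) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    fields[[key]] <- val
  }
  lapply(fields, function(v) trimws(gsub("[{}]", "", v)))
}

#' Write a cube as per-pixel CSV spectra with a JSON sidecar
#'
#' One pixel per CSV row (row-major order), header = band values; the
#' sidecar (`paste0(path, ".json")`) records the spatial shape, pixel size,
#' axis unit and modality needed to refold the spectra.
#'
#' @param cube A [chem_cube()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_csv_spectra <- function(cube, path) {
  stopifnot(inherits(cube, "chem_cube"))
  um <- unfold(cube)
  df <- as.data.frame(um$values)
  names(df) <- sprintf("%.10g", cube$axis$values)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(shape = dim(cube$data)[1:2], pixel_size_um = cube$pixel_size_um,
               unit = cube$axis$unit, modality = cube$modality,
               bad_pixels = which(cube$bad_pixel_mask, arr.ind = TRUE))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read per-pixel CSV spectra written by [write_csv_spectra()]
#'
#' @param path CSV path (sidecar expected at `paste0(path, ".json")`).
#' @return A [chem_cube()].
#' @export
read_csv_spectra <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df)
  ax <- spectral_axis(as.numeric(names(df)), meta$unit, meta$modality)
  shape <- as.integer(meta$shape)
  um <- structure(list(values = vals,
                       index_map = cbind(row = rep(seq_len(shape[1]), each = shape[2]),
                                         col = rep(seq_len(shape[2]), times = shape[1])),
                       shape = shape, axis = ax,
                       pixel_size_um = as.numeric(meta$pixel_size_um),
                       modality = meta$modality),
                  class = "unfolded")
  cube <- refold(um)
  if (length(meta$bad_pixels) && NROW(meta$bad_pixels) > 0) {
    bp <- matrix(as.integer(unlist(meta$bad_pixels)), ncol = 2)
    cube$bad_pixel_mask[bp] <- TRUE
  }
  cube
}
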