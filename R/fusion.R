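# Low-, mid- and high-level fusion of registered cubes, and the class-map
# utilities shared by the PLS-DA classification workflow.

#' Split a cube and its class map into train/test halves
#'
#' Deterministic spatial split at the image midline: one half for model
#' building, the other for prediction. Errors if any class present in the
#' full map is missing from either half. Within the training half the
#' calibration/validation sub-split is by interleaved pixel rows (handled
#' inside [plsda_fit()]).
#'
#' @param cube A [chem_cube()].
#' @param labels Integer class-map matrix (0 = unlabelled).
#' @param axis `"vertical"` splits into left/right halves, `"horizontal"`
#'   into top/bottom.
#' @return List of two lists (`train`, `test`), each with `$cube` and
#'   `$labels`.
#' @export
split_halves <- function(cube, labels, axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  stopifnot(inherits(cube, "chem_cube"), all(dim(labels) == dim(cube$data)[1:2]))
  d <- dim(cube$data)
  take <- function(rows, cols) {
    list(cube = chem_cube(cube$data[rows, cols, , drop = FALSE],
                          cube$axis, cube$pixel_size_um,
                          cube$bad_pixel_mask[rows, cols, drop = FALSE],
                          cube$modality),
         labels = labels[rows, cols, drop = FALSE])
  }
  if (axis == "vertical") {
    half <- d[2] %/% 2L
    out <- list(train = take(seq_len(d[1]), seq_len(half)),
                test = take(seq_len(d[1]), (half + 1L):d[2]))
  } else {
    half <- d[1] %/% 2L
    out <- list(train = take(seq_len(half), seq_len(d[2])),
                test = take((half + 1L):d[1], seq_len(d[2])))
  }
  classes <- sort(unique(labels[labels > 0]))
  for (h in out) {
    miss <- setdiff(classes, unique(h$labels[h$labels > 0]))
    if (length(miss))
      stop("class(es) ", paste(miss, collapse = ", "), " missing from one half")
  }
  out
}

#' Low-level fusion: concatenate two registered cubes along the band axis
#'
#' Each cube is unfolded, autoscaled, block-scaled (1/sqrt(bands), so the
#' modality with more spectral variables cannot dominate) and maximum-scaled,
#' then the blocks are concatenated. The composite [fused_axis()] tags each
#' band with its source modality and original band position.
#'
#' @param a,b Registered [chem_cube()]s with identical spatial shapes.
#' @return A fused [chem_cube()] with `bands_a + bands_b` channels; the
#'   scaling parameters are attached as attribute `"scaling"`.
#' @export
low_level_fuse <- function(a, b) {
  stopifnot(inherits(a, "chem_cube"), inherits(b, "chem_cube"))
  if (!all(dim(a$data)[1:2] == dim(b$data)[1:2]))
    stop("spatial shapes differ: register the cubes first")
  sc <- scale_blocks(list(unfold(a), unfold(b)))
  fused_vals <- cbind(sc$blocks[[1]]$values, sc$blocks[[2]]$values)
  bands <- rbind(
    data.frame(modality = a$modality, value = a$axis$values),
    data.frame(modality = b$modality, value = b$axis$values))
  um <- sc$blocks[[1]]
  um$values <- fused_vals
  um$axis <- fused_axis(bands, unit = a$axis$unit)
  um$modality <- um$axis$modality
  out <- refold(um)
  out$bad_pixel_mask <- a$bad_pixel_mask | b$bad_pixel_mask
  attr(out, "scaling") <- sc$params
  out
}

#' Mid-level fusion: concatenate per-modality PC score images
#'
#' PCA is applied to each cube separately and the leading score images are
#' stacked channel-wise; the channel table records modality, PC index and
#' explained variance.
#'
#' @param a,b Registered [chem_cube()]s with identical spatial shapes.
#' @param n_pcs Integer pair: components kept per modality (default 10, 10).
#' @return A fused [chem_cube()] with `sum(n_pcs)` channels.
#' @export
mid_level_fuse <- function(a, b, n_pcs = c(10L, 10L)) {
  stopifnot(inherits(a, "chem_cube"), inherits(b, "chem_cube"))
  if (!all(dim(a$data)[1:2] == dim(b$data)[1:2]))
    stop("spatial shapes differ: register the cubes first")
  n_pcs <- rep(as.integer(n_pcs), length.out = 2L)
  ua <- unfold(a); ub <- unfold(b)
  if (n_pcs[1] > min(dim(ua$values)) || n_pcs[2] > min(dim(ub$values)))
    stop("'n_pcs' exceeds the rank of a block")
  pa <- cube_pca(ua, n_pcs[1]); pb <- cube_pca(ub, n_pcs[2])
  bands <- rbind(
    data.frame(modality = a$modality, pc = seq_len(n_pcs[1]),
               var_pct = 100 * pa$explained),
    data.frame(modality = b$modality, pc = seq_len(n_pcs[2]),
               var_pct = 100 * pb$explained))
  um <- ua
  um$values <- cbind(pa$scores, pb$scores)
  um$axis <- fused_axis(bands, unit = a$axis$unit)
  um$modality <- um$axis$modality
  out <- refold(um)
  out$bad_pixel_mask <- a$bad_pixel_mask | b$bad_pixel_mask
  out
}

#' High-level (consensus) fusion of two class maps
#'
#' Pixels assigned the same class by both maps keep it; disagreeing pixels
#' become 0 (unknown).
#'
#' @param map_a,map_b Integer class-map matrices of identical shape.
#' @return Integer class-map matrix.
#' @export
consensus_fuse <- function(map_a, map_b) {
  if (!all(dim(map_a) == dim(map_b))) stop("class maps must share a shape")
  out <- map_a
  out[map_a != map_b] <- 0L
  out
}

#' Global percent correct classification
#'
#' `100 * #(pred == truth, truth != 0) / #(truth != 0)`; unlabelled truth
#' pixels are ignored and unknown (0) predictions count as incorrect.
#'
#' @param pred,truth Integer class-map matrices of identical shape.
#' @return Percentage in `[0, 100]`.
#' @export
classification_accuracy <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("class maps must share a shape")
  n <- sum(truth != 0)
  if (n == 0L) stop("no labelled pixels")
  100 * sum(pred == truth & truth != 0) / n
}
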