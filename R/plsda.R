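# PLS-DA pixel classification on unfolded data: PLS2 regression of a
# one-hot class indicator matrix on spectra, class = maximum predicted
# response. The latent-variable count is chosen on validation global
# percent correct classification.

pls_colnames <- function(m, prefix) {
  colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  m
}

# numerical rank of the column-centered matrix; caps the latent-variable
# search so NIPALS never runs past the information content of the data
effective_rank <- function(m) {
  d <- svd(sweep(m, 2L, colMeans(m)), nu = 0L, nv = 0L)$d
  if (d[1] == 0) return(0L)
  sum(d > max(dim(m)) * .Machine$double.eps * d[1] * 10)
}

#' Fit a PLS-DA pixel classifier
#'
#' The training rows are sub-split into calibration (odd rows) and
#' validation (even rows, interleaved). A PLS2 model of the one-hot class
#' indicators on the spectra is fitted to the calibration rows with up to
#' `max_lv` latent variables; the kept count is the smallest one whose
#' validation global percent correct classification is within 0.5
#' percentage points of the maximum. The final model is refitted on all
#' training rows with that count.
#'
#' @param X An [unfold()]ed matrix (or plain matrix) of training spectra.
#' @param labels Integer class labels per row (> 0; 0-labelled rows are
#'   dropped).
#' @param max_lv Maximum number of latent variables to consider.
#' @return A `plsda_model`: the fitted PLS object, `$n_lv`, `$classes`,
#'   `$val_accuracy` (per LV), `$n_bands`.
#' @export
plsda_fit <- function(X, labels, max_lv) {
  if (inherits(X, "unfolded")) X <- X$values
  labels <- as.integer(labels)
  if (max_lv < 1L) stop("'max_lv' must be at least 1")
  keep <- labels > 0L
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  sds <- apply(X, 2L, stats::sd)
  if (all(sds == 0)) stop("degenerate predictor matrix (no variance)")
  Y <- outer(labels, classes, `==`) * 1.0
  X <- pls_colnames(X, "b"); Y <- pls_colnames(Y, "cls")
  cal <- seq_along(labels) %% 2L == 1L
  max_lv <- min(as.integer(max_lv), nrow(X) - 1L, ncol(X),
                effective_rank(X[cal, , drop = FALSE]))
  if (max_lv < 1L) stop("degenerate predictor matrix (no variance)")
  fit_cal <- mixOmics::pls(X[cal, , drop = FALSE], Y[cal, , drop = FALSE],
                           ncomp = max_lv, scale = FALSE, mode = "regression")
  pred <- predict(fit_cal, X[!cal, , drop = FALSE])$predict
  val_acc <- vapply(seq_len(max_lv), function(lv) {
    resp <- matrix(pred[, , lv], ncol = length(classes))
    cl <- classes[max.col(resp, ties.method = "first")]
    100 * mean(cl == labels[!cal])
  }, numeric(1))
  n_lv <- which(val_acc >= max(val_acc) - 0.5)[1]
  fit <- mixOmics::pls(X, Y, ncomp = n_lv, scale = FALSE, mode = "regression")
  structure(list(fit = fit, n_lv = n_lv, classes = classes,
                 val_accuracy = val_acc, n_bands = ncol(X)),
            class = "plsda_model")
}

#' Predict pixel classes with a PLS-DA model
#'
#' Per-pixel responses from the PLS model; class = argmax response, ties
#' broken by the lowest class index. Probabilities are the responses
#' clipped to `[0, 1]` and renormalised per pixel (uniform when all
#' responses clip to zero).
#'
#' @param model A [plsda_fit()] model.
#' @param x A [chem_cube()], [unfold()]ed matrix or plain matrix.
#' @return For a cube: list with `$class_map` (integer matrix, bad pixels
#'   0) and `$probabilities` (a [chem_cube()] of class probabilities). For
#'   a matrix: list with `$class` (vector) and `$probabilities` (matrix).
#' @export
plsda_predict <- function(model, x) {
  stopifnot(inherits(model, "plsda_model"))
  um <- NULL
  if (inherits(x, "chem_cube")) um <- unfold(x, exclude_bad = TRUE)
  if (inherits(x, "unfolded")) um <- x
  m <- if (is.null(um)) x else um$values
  if (ncol(m) != model$n_bands)
    stop(sprintf("band count mismatch: model has %d, data has %d",
                 model$n_bands, ncol(m)))
  m <- pls_colnames(m, "b")
  resp <- predict(model$fit, m)$predict[, , model$n_lv]
  resp <- matrix(resp, nrow = nrow(m))
  cls <- model$classes[max.col(resp, ties.method = "first")]
  prob <- pmin(pmax(resp, 0), 1)
  rs <- rowSums(prob)
  prob[rs == 0, ] <- 1 / ncol(prob)
  rs[rs == 0] <- 1
  prob <- prob / rowSums(prob)
  if (is.null(um) || !inherits(x, "chem_cube"))
    return(list(class = cls, probabilities = prob))
  cmap <- matrix(0L, um$shape[1], um$shape[2])
  cmap[um$index_map] <- cls
  pum <- um
  pum$values <- prob
  pcube <- refold(pum, fill = 0,
                  axis = fused_axis(data.frame(modality = "class",
                                               class = model$classes)))
  list(class_map = cmap, probabilities = pcube)
}

#' Train and evaluate a PLS-DA classifier on a labelled cube
#'
#' Convenience wrapper for the half-split workflow: split the cube at the
#' midline, fit on the training half (with the interleaved
#' calibration/validation sub-split of [plsda_fit()]), predict the held-out
#' half and report the global percent correct classification.
#'
#' @param cube A [chem_cube()] (possibly a fused cube).
#' @param labels Integer class-map matrix.
#' @param max_lv Maximum latent variables.
#' @param split_axis Passed to [split_halves()].
#' @return List: `model`, `accuracy` (held-out %), `class_map` (predicted
#'   map of the test half), `truth` (test-half labels), `n_lv`.
#' @export
classify_cube <- function(cube, labels, max_lv = 20L, split_axis = "vertical") {
  halves <- split_halves(cube, labels, split_axis)
  utr <- unfold(halves$train$cube, exclude_bad = TRUE)
  ltr <- halves$train$labels[utr$index_map]
  model <- plsda_fit(utr, ltr, max_lv)
  pred <- plsda_predict(model, halves$test$cube)
  list(model = model,
       accuracy = classification_accuracy(pred$class_map, halves$test$labels),
       class_map = pred$class_map, truth = halves$test$labels,
       n_lv = model$n_lv)
}
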