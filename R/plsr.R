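# Cross-modality PLS regression: predict one modality's band intensities
# from the other's spectra over registered pixels.

#' Fit a cross-modality PLSR model
#'
#' Pixel rows are partitioned deterministically into calibration (fit),
#' validation (latent-variable selection) and test thirds by row index
#' modulo 3. The kept latent-variable count is the smallest one whose
#' validation RMSE is within 2% of the minimum (a parsimony rule); the
#' test partition is never touched during selection and its per-band R2 is
#' stored for reporting. The final model is refitted on the calibration +
#' validation rows.
#'
#' @param X,Y [unfold()]ed matrices (or plain matrices) over the same
#'   registered pixels: predictors and targets.
#' @param max_lv Maximum latent variables to consider.
#' @return A `plsr_model`: fitted PLS object, `$n_lv`, `$val_rmse` (per
#'   LV), `$test_r2` (per target band), `$test_rows`, axes bookkeeping.
#' @export
plsr_fit <- function(X, Y, max_lv) {
  x_axis <- if (inherits(X, "unfolded")) X$axis else NULL
  y_axis <- if (inherits(Y, "unfolded")) Y$axis else NULL
  if (inherits(X, "unfolded")) X <- X$values
  if (inherits(Y, "unfolded")) Y <- Y$values
  if (nrow(X) != nrow(Y)) stop("X and Y must share pixels")
  if (max_lv < 1L) stop("'max_lv' must be at least 1")
  X <- pls_colnames(as.matrix(X), "x"); Y <- pls_colnames(as.matrix(Y), "y")
  fold <- (seq_len(nrow(X)) - 1L) %% 3L     # 0 = cal, 1 = val, 2 = test
  cal <- fold == 0L; val <- fold == 1L; tst <- fold == 2L
  max_lv <- min(as.integer(max_lv), sum(cal) - 1L, ncol(X),
                effective_rank(X[cal, , drop = FALSE]))
  if (max_lv < 1L) stop("degenerate predictor matrix (no variance)")
  fit_cal <- mixOmics::pls(X[cal, , drop = FALSE], Y[cal, , drop = FALSE],
                           ncomp = max_lv, scale = FALSE, mode = "regression")
  pv <- predict(fit_cal, X[val, , drop = FALSE])$predict
  val_rmse <- vapply(seq_len(max_lv), function(lv)
    sqrt(mean((matrix(pv[, , lv], ncol = ncol(Y)) - Y[val, ])^2)), numeric(1))
  n_lv <- which(val_rmse <= 1.02 * min(val_rmse))[1]
  dev <- cal | val
  fit <- mixOmics::pls(X[dev, , drop = FALSE], Y[dev, , drop = FALSE],
                       ncomp = n_lv, scale = FALSE, mode = "regression")
  pt <- predict(fit, X[tst, , drop = FALSE])$predict[, , n_lv]
  pt <- matrix(pt, ncol = ncol(Y))
  ss_res <- colSums((pt - Y[tst, , drop = FALSE])^2)
  ss_tot <- colSums(sweep(Y[tst, , drop = FALSE], 2L,
                          colMeans(Y[tst, , drop = FALSE]))^2)
  test_r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  structure(list(fit = fit, n_lv = n_lv, val_rmse = val_rmse,
                 test_r2 = test_r2, n_bands_in = ncol(X),
                 n_bands_out = ncol(Y), x_axis = x_axis, y_axis = y_axis),
            class = "plsr_model")
}

#' Predict target-modality intensities from predictor spectra
#'
#' @param model A [plsr_fit()] model.
#' @param X An [unfold()]ed matrix (or plain matrix) of predictor spectra.
#' @param targets `NULL` for all output bands, or band positions on the
#'   target axis (nearest-band lookup).
#' @return If `X` is unfolded, an `unfolded` matrix (refoldable to an
#'   image); otherwise a plain matrix. One column per requested band.
#' @export
plsr_predict <- function(model, X, targets = NULL) {
  stopifnot(inherits(model, "plsr_model"))
  um <- if (inherits(X, "unfolded")) X else NULL
  m <- if (is.null(um)) as.matrix(X) else um$values
  if (ncol(m) != model$n_bands_in)
    stop(sprintf("band count mismatch: model takes %d, data has %d",
                 model$n_bands_in, ncol(m)))
  m <- pls_colnames(m, "x")
  pred <- predict(model$fit, m)$predict[, , model$n_lv]
  pred <- matrix(pred, nrow = nrow(m))
  idx <- seq_len(model$n_bands_out)
  if (!is.null(targets)) {
    if (is.null(model$y_axis)) stop("model has no target axis; use band indices")
    idx <- vapply(targets, function(t) nearest_band(model$y_axis, t), integer(1))
  }
  pred <- pred[, idx, drop = FALSE]
  if (is.null(um)) return(pred)
  out <- um
  out$values <- pred
  if (!is.null(model$y_axis)) {
    out$axis <- axis_subset(model$y_axis, idx)
    out$modality <- model$y_axis$modality
  } else {
    out$axis <- index_axis(length(idx), "predicted")
  }
  out
}

#' Percent relative error spectrum between actual and predicted cubes
#'
#' Computed on the mean spectra (mean over pixels):
#' `100 * |mean_pred - mean_actual| / |mean_actual|` per band. Bands whose
#' actual mean magnitude is below `1e-12 * max |mean|` are flagged
#' undefined (`NA`). With `per_pixel = TRUE` the mean absolute per-pixel
#' relative error is returned instead.
#'
#' @param actual,predicted [chem_cube()]s (or `unfolded` matrices) of
#'   identical shape.
#' @param per_pixel Use the per-pixel definition.
#' @return Numeric vector of percent errors, one per band.
#' @export
relative_error_spectrum <- function(actual, predicted, per_pixel = FALSE) {
  get_vals <- function(x) {
    if (inherits(x, "chem_cube")) unfold(x)$values
    else if (inherits(x, "unfolded")) x$values
    else as.matrix(x)
  }
  a <- get_vals(actual); p <- get_vals(predicted)
  if (!all(dim(a) == dim(p))) stop("shapes differ")
  if (per_pixel) {
    eps <- 1e-12 * max(abs(a))
    rel <- 100 * abs(p - a) / pmax(abs(a), eps)
    return(colMeans(rel))
  }
  ma <- colMeans(a); mp <- colMeans(p)
  eps <- 1e-12 * max(abs(ma))
  out <- 100 * abs(mp - ma) / abs(ma)
  out[abs(ma) < eps] <- NA_real_
  out
}

#' Resolution enhancement by cross-modality prediction
#'
#' Applies a PLSR model trained on registered (down-sampled) data to the
#' original high-resolution cube of the predictor modality, after PCA
#' denoising (truncated reconstruction), yielding the target modality on
#' the high-resolution grid — the pansharpening-style step.
#'
#' @param model A [plsr_fit()] model (predictor = the high-resolution
#'   modality).
#' @param high_res_cube The original high-resolution predictor cube.
#' @param denoise_components Principal components kept in the denoising
#'   reconstruction (default 10); must not exceed the cube's rank.
#' @param targets Optional target band positions (see [plsr_predict()]).
#' @return A [chem_cube()] on the high-resolution grid with the target
#'   modality's bands.
#' @export
enhance_resolution <- function(model, high_res_cube, denoise_components = 10L,
                               targets = NULL) {
  stopifnot(inherits(model, "plsr_model"), inherits(high_res_cube, "chem_cube"))
  um0 <- unfold(high_res_cube)
  if (denoise_components > min(dim(um0$values)))
    stop("'denoise_components' exceeds the cube rank")
  den <- pca_denoise(high_res_cube, denoise_components)
  um <- unfold(den)
  pred <- plsr_predict(model, um, targets = targets)
  idx <- if (is.null(targets)) seq_len(model$n_bands_out)
         else vapply(targets, function(t) nearest_band(model$y_axis, t), integer(1))
  ax <- if (!is.null(model$y_axis)) axis_subset(model$y_axis, idx)
        else index_axis(length(idx), "predicted")
  refold(pred, axis = ax)
}

# degenerate-friendly axis of band indices (used for single-band results,
# where the strict spectral_axis() constructor does not apply)
index_axis <- function(n, modality = "") {
  structure(list(values = as.numeric(seq_len(n)), unit = "wavenumber",
                 modality = modality),
            class = "spectral_axis")
}
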