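#' Principal component analysis of an unfolded cube
#'
#' Mean-centers the (pixels x bands) matrix and computes its SVD. Loadings
#' are orthonormal, components are ordered by decreasing explained variance
#' and carry a deterministic sign: the largest-magnitude loading element of
#' each component is positive.
#'
#' @param um An [unfold()]ed matrix.
#' @param n_components Number of components to keep.
#' @return A `latent_model` with `$scores` (pixels x k), `$loadings`
#'   (bands x k), `$center`, `$eigenvalues` (variances along each
#'   component, n - 1 denominator) and `$explained` (fraction of total
#'   variance per kept component).
#' @export
cube_pca <- function(um, n_components) {
  stopifnot(inherits(um, "unfolded"))
  x <- um$values
  k <- as.integer(n_components)
  if (k < 1L || k > min(dim(x))) stop("'n_components' out of range")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = k, nv = k)
  ev_all <- sv$d^2 / (nrow(x) - 1)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v
  for (j in seq_len(k)) {            # deterministic sign convention
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings, center = mu,
                 eigenvalues = ev_all[seq_len(k)],
                 explained = ev_all[seq_len(k)] / sum(ev_all),
                 n_components = k,
                 index_map = um$index_map, shape = um$shape),
            class = "latent_model")
}

#' Refold PCA score images
#'
#' @param model A `latent_model` from [cube_pca()].
#' @param component Component index.
#' @return A numeric rows x cols matrix (excluded pixels are `NA`).
#' @export
score_image <- function(model, component = 1L) {
  stopifnot(inherits(model, "latent_model"))
  if (component < 1L || component > model$n_components)
    stop("component out of range")
  img <- matrix(NA_real_, model$shape[1], model$shape[2])
  img[model$index_map] <- model$scores[, component]
  img
}

#' Denoise a cube by truncated PCA reconstruction
#'
#' Reconstructs the cube from its leading principal components
#' (scores %*% t(loadings) + mean), the compression step used to de-noise
#' high-resolution spectra before cross-modality prediction.
#'
#' @param cube A [chem_cube()].
#' @param n_components Number of components used for reconstruction
#'   (default 10).
#' @return A [chem_cube()] with the same shape and axis.
#' @export
pca_denoise <- function(cube, n_components = 10L) {
  stopifnot(inherits(cube, "chem_cube"))
  um <- unfold(cube)
  if (n_components > min(dim(um$values)))
    stop("'n_components' exceeds the matrix dimensions")
  p <- cube_pca(um, n_components)
  rec <- p$scores %*% t(p$loadings)
  rec <- sweep(rec, 2L, p$center, "+")
  out <- um
  out$values <- rec
  refold(out)
}
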