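# Multiblock co-inertia analysis of registered, unfolded cubes. Each
# component is the dominant singular triplet of the column-centered
# concatenated blocks: the unit global loading u maximises the covariance
# structure captured by the global score s = X u. Block loadings are the
# partition of u over the block band ranges, block scores are X_k u_k, and
# after each component every block is deflated by regression on the global
# score. Block contribution metrics quantify each modality's share of the
# common structure.

#' Fit a multiblock co-inertia model
#'
#' @param blocks List of [unfold()]ed matrices (or plain matrices) sharing
#'   the same pixel rows. Blocks are column-centered internally; apply
#'   [scale_blocks()] first for the standard pre-fusion scaling.
#' @param n_components Number of components to extract.
#' @param center Column-center the blocks (default `TRUE`; kept as an
#'   escape hatch for pre-centered input).
#' @return A `coinertia` object: `$global_scores` (pixels x C),
#'   `$global_loadings` ((sum of bands) x C, unit columns), `$block_scores`
#'   (list of pixels x C), `$block_loadings` (list), `$eigenvalues`
#'   (squared singular values), `$block_index` (band -> block map),
#'   `$shape`/`$index_map` bookkeeping when available.
#' @export
coinertia_fit <- function(blocks, n_components, center = TRUE) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  meta <- blocks[[1]]
  mats <- lapply(blocks, function(b) if (inherits(b, "unfolded")) b$values else as.matrix(b))
  np <- vapply(mats, nrow, integer(1))
  if (length(unique(np)) != 1L) stop("blocks must share the same pixels")
  if (center) mats <- lapply(mats, function(m) sweep(m, 2L, colMeans(m)))
  nb <- vapply(mats, ncol, integer(1))
  K <- length(mats)
  X <- do.call(cbind, mats)
  if (max(abs(X)) == 0) stop("zero data matrix")
  C <- as.integer(n_components)
  if (C < 1L || C > min(dim(X))) stop("'n_components' out of range")
  block_index <- rep(seq_len(K), times = nb)
  n <- nrow(X)
  gs <- matrix(0, n, C)
  gl <- matrix(0, sum(nb), C)
  bs <- lapply(seq_len(K), function(k) matrix(0, n, C))
  bl <- lapply(seq_len(K), function(k) matrix(0, nb[k], C))
  ev <- numeric(C)
  for (comp in seq_len(C)) {
    sv <- svd(do.call(cbind, mats), nu = 1L, nv = 1L)
    u <- sv$v[, 1]
    s <- do.call(cbind, mats) %*% u       # = d1 * u1
    i <- which.max(abs(s))                # deterministic sign on the score
    if (s[i] < 0) { s <- -s; u <- -u }
    gs[, comp] <- s
    gl[, comp] <- u
    ev[comp] <- sv$d[1]^2
    for (k in seq_len(K)) {
      uk <- u[block_index == k]
      bl[[k]][, comp] <- uk
      bs[[k]][, comp] <- mats[[k]] %*% uk
      # deflate block k by regression on the global score
      beta <- crossprod(s, mats[[k]]) / sum(s^2)
      mats[[k]] <- mats[[k]] - s %*% beta
    }
  }
  structure(list(global_scores = gs, global_loadings = gl,
                 block_scores = bs, block_loadings = bl,
                 eigenvalues = ev, block_index = block_index,
                 n_components = C, n_blocks = K, n_bands = nb,
                 shape = if (inherits(meta, "unfolded")) meta$shape else NULL,
                 index_map = if (inherits(meta, "unfolded")) meta$index_map else NULL),
            class = "coinertia")
}

#' @export
print.coinertia <- function(x, ...) {
  cat(sprintf("<coinertia> %d blocks (%s bands), %d components\n",
              x$n_blocks, paste(x$n_bands, collapse = "+"), x$n_components))
  invisible(x)
}

#' Contribution of a block's loadings to the global loading (%)
#'
#' `100 * ||u_k||^2 / ||u||^2`; since the global loading has unit norm the
#' contributions sum to exactly 100 over blocks for every component.
#'
#' @param result A [coinertia_fit()] result.
#' @param k Block index.
#' @param c Component index.
#' @return Percentage.
#' @export
block_loading_contribution <- function(result, k, c) {
  stopifnot(inherits(result, "coinertia"))
  uk <- result$block_loadings[[k]][, c]
  u <- result$global_loadings[, c]
  100 * sum(uk^2) / sum(u^2)
}

#' Contribution of a block's component to the global component (%)
#'
#' `100 * cov^2(s_k, s) / sum_k var(s_k)^2`. Unlike the loading
#' contributions these do not sum to 100 over blocks; their total measures
#' how much of the global component is common structure.
#'
#' @inheritParams block_loading_contribution
#' @return Percentage.
#' @export
block_component_contribution <- function(result, k, c) {
  stopifnot(inherits(result, "coinertia"))
  s <- result$global_scores[, c]
  sk <- result$block_scores[[k]][, c]
  vs <- vapply(result$block_scores, function(b) stats::var(b[, c]), numeric(1))
  if (stats::var(sk) == 0) {
    warning("block score has zero variance; contribution reported as 0")
    return(0)
  }
  100 * stats::cov(sk, s)^2 / sum(vs^2)
}

#' Pearson correlation between block and global scores
#'
#' @inheritParams block_loading_contribution
#' @return Correlation in `[-1, 1]`.
#' @export
block_global_correlation <- function(result, k, c) {
  stopifnot(inherits(result, "coinertia"))
  sk <- result$block_scores[[k]][, c]
  if (stats::sd(sk) == 0) stop("block score is constant; correlation undefined")
  stats::cor(sk, result$global_scores[, c])
}

#' Co-inertia block metric table
#'
#' One row per metric (loading contribution, component contribution and
#' block-global correlation, for each block), one column per component —
#' the standard summary layout for a two-block analysis.
#'
#' @param result A [coinertia_fit()] result.
#' @param block_names Optional block labels.
#' @return A data.frame (metrics x components).
#' @export
coinertia_metrics <- function(result, block_names = NULL) {
  stopifnot(inherits(result, "coinertia"))
  K <- result$n_blocks; C <- result$n_components
  if (is.null(block_names)) block_names <- paste0("block", seq_len(K))
  rows <- list()
  for (k in seq_len(K))
    rows[[sprintf("Contribution of %s loadings to global loadings (%%)", block_names[k])]] <-
      vapply(seq_len(C), function(c) block_loading_contribution(result, k, c), numeric(1))
  for (k in seq_len(K))
    rows[[sprintf("Contribution of %s components to global components (%%)", block_names[k])]] <-
      vapply(seq_len(C), function(c) block_component_contribution(result, k, c), numeric(1))
  for (k in seq_len(K))
    rows[[sprintf("Correlation between %s block scores and global scores", block_names[k])]] <-
      vapply(seq_len(C), function(c) block_global_correlation(result, k, c), numeric(1))
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- paste0("comp", seq_len(C))
  out
}

#' Refold a co-inertia score vector into an image
#'
#' @param result A [coinertia_fit()] result built from unfolded cubes.
#' @param component Component index.
#' @param block `NULL` for the global score, or a block index.
#' @return Numeric score image.
#' @export
coinertia_score_image <- function(result, component = 1L, block = NULL) {
  stopifnot(inherits(result, "coinertia"))
  if (is.null(result$shape)) stop("result carries no spatial bookkeeping")
  v <- if (is.null(block)) result$global_scores[, component]
       else result$block_scores[[block]][, component]
  img <- matrix(NA_real_, result$shape[1], result$shape[2])
  img[result$index_map] <- v
  img
}
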