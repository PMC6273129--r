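#' Detect bad pixels from per-pixel summary statistics
#'
#' Flags detector faults: pixels whose summary statistics (median intensity
#' and log spectral variance) deviate from their 3x3 spatial neighbourhood
#' median by more than `z_threshold` robust z-units (scale estimated by the
#' MAD of the residual image), plus dead pixels whose spectrum is constant
#' (zero spectral variance). Comparing against the local neighbourhood
#' keeps genuine, spatially smooth sample structure from being flagged.
#'
#' @param cube A [chem_cube()].
#' @param z_threshold Robust z-units beyond which a pixel is flagged.
#' @return Logical rows x cols matrix (`TRUE` = bad).
#' @export
detect_bad_pixels <- function(cube, z_threshold = 5) {
  stopifnot(inherits(cube, "chem_cube"))
  d <- dim(cube$data)
  if (d[1] * d[2] < 9L) stop("need at least 9 pixels")
  um <- unfold(cube)
  if (max(um$values) == min(um$values)) {
    warning("constant cube: no pixel is distinguishable, nothing flagged")
    return(matrix(FALSE, d[1], d[2]))
  }
  med <- matrix(apply(um$values, 1L, stats::median), d[1], d[2], byrow = TRUE)
  v <- matrix(apply(um$values, 1L, stats::var), d[1], d[2], byrow = TRUE)
  outlier <- function(img) {
    res <- img - median_filter3(img)
    # scale: MAD of the residual, floored at 5% of the statistic's dynamic
    # range: detector faults are gross outliers, smooth-field curvature and
    # sample texture are not
    s <- max(stats::mad(res), 0.05 * diff(range(img)))
    if (s == 0) return(matrix(FALSE, d[1], d[2]))
    abs(res) / s > z_threshold
  }
  outlier(med) | outlier(log1p(v - min(v))) | v == 0
}

# 3x3 spatial median filter with replicated edges
median_filter3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  shift <- function(dr, dc)
    img[pmin(pmax(seq_len(nr) + dr, 1L), nr),
        pmin(pmax(seq_len(nc) + dc, 1L), nc), drop = FALSE]
  stack <- vapply(seq_len(9L), function(i) {
    dr <- (i - 1L) %/% 3L - 1L
    dc <- (i - 1L) %% 3L - 1L
    shift(dr, dc)
  }, matrix(0, nr, nc))
  apply(stack, c(1, 2), stats::median)
}

#' Savitzky-Golay second derivative of unfolded spectra
#'
#' Applies the classical windowed polynomial-smoothing second derivative to
#' every spectrum (matrix row), with respect to the band index on a unit
#' grid. Only interior bands where the full window fits are returned: the
#' spectral axis is trimmed by `(window - 1) / 2` bands at each end, so no
#' boundary derivatives are fabricated.
#'
#' @param um An [unfold()]ed matrix.
#' @param window Odd window length (default 15).
#' @param polyorder Polynomial order (default 3; must be >= 2).
#' @return An `unfolded` object with `bands - window + 1` columns and a
#'   trimmed axis.
#' @export
savgol_second_derivative <- function(um, window = 15L, polyorder = 3L) {
  stopifnot(inherits(um, "unfolded"))
  nb <- ncol(um$values)
  if (window %% 2L != 1L) stop("'window' must be odd")
  if (polyorder < 2L) stop("'polyorder' must be >= 2 for a 2nd derivative")
  if (polyorder >= window) stop("'polyorder' must be < 'window'")
  if (window > nb) stop(sprintf("window (%d) exceeds band count (%d)", window, nb))
  h <- (window - 1L) / 2L
  cc <- signal::sgolay(p = polyorder, n = window, m = 2L)[h + 1L, ]
  # banded band-transform matrix: out band j <- in bands j .. j + window - 1
  n_out <- nb - window + 1L
  Tm <- matrix(0, nb, n_out)
  for (j in seq_len(n_out)) Tm[j:(j + window - 1L), j] <- cc
  out <- um
  out$values <- um$values %*% Tm
  out$axis <- axis_subset(um$axis, (h + 1L):(nb - h))
  out
}

#' Autoscale the columns of an unfolded matrix
#'
#' Centers every band (column) to mean 0 and scales it to unit sample
#' standard deviation (n - 1 denominator), the usual chemometric
#' column-autoscaling applied before fusion.
#'
#' @param um An [unfold()]ed matrix.
#' @return List with `$matrix` (scaled `unfolded`) and `$params`
#'   (`scaling_params` holding the per-band mean/sd; see
#'   [inverse_autoscale()]).
#' @export
autoscale <- function(um) {
  stopifnot(inherits(um, "unfolded"))
  mu <- colMeans(um$values)
  sd_ <- apply(um$values, 2L, stats::sd)
  if (any(sd_ == 0)) {
    bad <- which(sd_ == 0)[1]
    stop(sprintf("band %g (column %d) has zero variance and cannot be autoscaled",
                 um$axis$values[bad], bad))
  }
  out <- um
  out$values <- sweep(sweep(um$values, 2L, mu), 2L, sd_, "/")
  params <- structure(list(mean = mu, sd = sd_, steps = "autoscale"),
                      class = "scaling_params")
  list(matrix = out, params = params)
}

#' Undo autoscaling
#'
#' @param um Autoscaled `unfolded` matrix.
#' @param params The `scaling_params` returned by [autoscale()].
#' @return The original-scale `unfolded` matrix.
#' @export
inverse_autoscale <- function(um, params) {
  out <- um
  out$values <- sweep(sweep(um$values, 2L, params$sd, "*"), 2L, params$mean, "+")
  out
}

#' Block and maximum scaling of multiple data blocks
#'
#' Divides each (autoscaled) block by the square root of its band count so
#' that blocks with many spectral variables cannot dominate a joint model
#' (total sum of squares equalised), then divides each block by its maximum
#' absolute value ("maximum scaling"). Both parameter sets are stored.
#'
#' @param blocks List of [unfold()]ed matrices sharing the same pixels.
#' @return List with `$blocks` (scaled list) and `$params`.
#' @export
block_and_max_scale <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  np <- vapply(blocks, function(b) nrow(b$values), integer(1))
  if (length(unique(np)) != 1L) stop("blocks must share the same pixels")
  if (any(vapply(blocks, function(b) ncol(b$values) == 0L, logical(1))))
    stop("empty block")
  w <- vapply(blocks, function(b) 1 / sqrt(ncol(b$values)), numeric(1))
  scaled <- mapply(function(b, wi) { b$values <- b$values * wi; b },
                   blocks, w, SIMPLIFY = FALSE)
  mx <- vapply(scaled, function(b) max(abs(b$values)), numeric(1))
  mx[mx == 0] <- 1
  scaled <- mapply(function(b, mi) { b$values <- b$values / mi; b },
                   scaled, mx, SIMPLIFY = FALSE)
  params <- structure(list(block_weight = w, max_abs = mx,
                           steps = c("block", "max")),
                      class = "scaling_params")
  list(blocks = scaled, params = params)
}

#' Standard pre-fusion scaling stack
#'
#' Autoscale each block, then block-scale and maximum-scale the set — the
#' scaling sequence applied before low-level fusion and co-inertia analysis.
#'
#' @param blocks List of [unfold()]ed matrices.
#' @return List with `$blocks` and `$params` (list of per-step params).
#' @export
scale_blocks <- function(blocks) {
  a <- lapply(blocks, autoscale)
  bm <- block_and_max_scale(lapply(a, `[[`, "matrix"))
  list(blocks = bm$blocks,
       params = list(autoscale = lapply(a, `[[`, "params"),
                     block_max = bm$params))
}
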