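# Five-step multivariate registration of a high-resolution cube onto a
# low-resolution cube's pixel grid: (1) PCA per cube, (2) histogram
# thresholding of the selected score images into binary masks, (3) rotation/
# flipping and bicubic down-sampling of the high-resolution target, (4)
# affine optimisation by regular-step gradient descent on the mean square
# difference, (5) slice-wise application of the whole pipeline to the cube.

#' Threshold a score image into a binary mask
#'
#' @param score_image Numeric matrix (e.g. a PC score image).
#' @param method `"otsu"` (histogram-based, 256 bins) or `"manual"`.
#' @param manual_value Threshold for `method = "manual"`.
#' @param invert Invert the mask polarity (select pixels below threshold).
#' @return A `binary_mask`: logical matrix with attributes `threshold` and
#'   `method`. Errors if the mask would be all-`TRUE` or all-`FALSE`.
#' @export
threshold_mask <- function(score_image, method = c("otsu", "manual"),
                           manual_value = NULL, invert = FALSE) {
  method <- match.arg(method)
  x <- score_image[is.finite(score_image)]
  if (method == "otsu") {
    if (max(x) == min(x)) stop("constant image: Otsu threshold is undefined")
    thr <- otsu_threshold(x)
  } else {
    if (is.null(manual_value)) stop("'manual_value' required for manual thresholding")
    thr <- manual_value
  }
  mask <- score_image > thr
  if (invert) mask <- !mask
  mask[!is.finite(score_image)] <- FALSE
  if (!any(mask) || all(mask[is.finite(score_image)]))
    stop("degenerate mask: threshold leaves no foreground/background split")
  structure(mask, threshold = thr, method = method, class = c("binary_mask", "matrix"))
}

# Otsu's method on a 256-bin histogram: threshold maximising between-class
# variance; returns the bin edge.
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  h <- tabulate(pmin(pmax(floor((x - rng[1]) / diff(rng) * nbins) + 1L, 1L),
                     nbins), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b[-nbins])
  rng[1] + k / nbins * diff(rng)
}

#' Orient and resize an image
#'
#' Applies quarter-turn rotation, then flips, then resizing to the target
#' shape (bicubic with antialiasing by default) — step 3 of the
#' registration workflow.
#'
#' @param img Numeric matrix.
#' @param rot90_quarter_turns Counterclockwise quarter turns (mod 4).
#' @param flip_axes Subset of `c("vertical", "horizontal")`.
#' @param target_shape Output `(rows, cols)`; defaults to the oriented shape.
#' @param interpolation Passed to [resize_image()].
#' @return Matrix of dimension `target_shape`.
#' @export
orient_and_resize <- function(img, rot90_quarter_turns = 0L,
                              flip_axes = character(), target_shape = NULL,
                              interpolation = "bicubic") {
  img <- flip_image(rot90_image(img, rot90_quarter_turns), flip_axes)
  if (is.null(target_shape)) return(img)
  if (all(dim(img) == target_shape)) return(img)
  resize_image(img, target_shape, interpolation)
}

#' Mean square difference between two images
#'
#' @param a,b Numeric matrices of the same shape.
#' @param mask Optional logical matrix restricting the mean.
#' @return Mean over (masked) pixels of `(a - b)^2`.
#' @export
mean_square_difference <- function(a, b, mask = NULL) {
  if (!all(dim(a) == dim(b))) stop("images must share a shape")
  d2 <- (a - b)^2
  if (is.null(mask)) return(mean(d2))
  if (!any(mask)) stop("empty mask")
  mean(d2[mask])
}

#' Default optimizer settings for [register_affine()]
#'
#' @param max_step Initial/maximum step length in (scaled) parameter space.
#' @param min_step Convergence threshold on the step length.
#' @param relaxation Step shrink factor applied when the gradient direction
#'   reverses.
#' @param max_iterations Iteration cap per descent run.
#' @param restarts Number of times the descent is restarted from the best
#'   point found with the step length reset to `max_step` (escapes
#'   premature step collapse in narrow valleys).
#' @return A named list.
#' @export
regular_step_optimizer <- function(max_step = 0.0625, min_step = 1e-5,
                                   relaxation = 0.5, max_iterations = 300L,
                                   restarts = 2L) {
  list(max_step = max_step, min_step = min_step, relaxation = relaxation,
       max_iterations = as.integer(max_iterations),
       restarts = as.integer(restarts))
}

# 6-parameter vector -> homogeneous affine. Translation parameters are
# scaled by half the image extent so all parameters share a magnitude.
params_to_affine <- function(p, tscale) {
  matrix(c(1 + p[1], p[2],     p[5] * tscale,
           p[3],     1 + p[4], p[6] * tscale,
           0,        0,        1),
         3L, 3L, byrow = TRUE)
}

#' Optimise an affine transform between two images
#'
#' Minimises the mean square difference between `fixed` and the
#' affine-warped `moving` image (bilinear resampling, center-origin pixel
#' coordinates) by regular-step gradient descent: the step length shrinks
#' by `relaxation` whenever the gradient direction reverses, and the search
#' stops at `min_step` or `max_iterations`. Gradients are central finite
#' differences on the 6 affine parameters. With `dof = "similarity"` the
#' linear part is restricted to rotation + isotropic scale.
#'
#' @param fixed,moving Numeric matrices of the same shape, non-constant.
#' @param optimizer Settings from [regular_step_optimizer()].
#' @param dof `"affine"` (6 parameters) or `"similarity"` (4).
#' @param init Optional 3x3 affine used as the starting transform
#'   (`dof = "affine"` only); the usual source is a similarity-stage fit.
#' @return List: `affine` (3x3, maps fixed to moving coordinates),
#'   `final_msd`, `converged`, `trace` (per-iteration MSD).
#' @export
register_affine <- function(fixed, moving,
                            optimizer = regular_step_optimizer(),
                            dof = c("affine", "similarity"), init = NULL) {
  dof <- match.arg(dof)
  if (!all(dim(fixed) == dim(moving))) stop("images must share a shape (resize first)")
  if (max(fixed) == min(fixed) || max(moving) == min(moving))
    stop("constant image cannot be registered")
  fixed <- matrix(as.numeric(fixed), nrow(fixed), ncol(fixed))
  moving <- matrix(as.numeric(moving), nrow(moving), ncol(moving))
  tscale <- max(dim(fixed)) / 2
  expand <- function(q) {                 # similarity: (angle, log-scale, tr, tc)
    if (dof == "affine") return(q)
    s <- exp(q[2]); a <- q[1]
    c(s * cos(a) - 1, -s * sin(a), s * sin(a), s * cos(a) - 1, q[3], q[4])
  }
  loss <- function(q) {
    A <- params_to_affine(expand(q), tscale)
    w <- warp_affine(moving, A, out_shape = dim(fixed), fill = 0)
    ok <- attr(w, "valid")
    # restrict to in-view pixels: makes the metric invariant to adding a
    # constant to both images and keeps borders from dominating
    v <- if (all(ok)) mean((fixed - w)^2) else mean((fixed[ok] - w[ok])^2)
    if (!is.finite(v)) stop("non-finite registration loss")
    v
  }
  np <- if (dof == "affine") 6L else 4L
  q <- numeric(np)
  if (!is.null(init)) {
    if (dof != "affine") stop("'init' is only supported for dof = \"affine\"")
    q <- c(init[1, 1] - 1, init[1, 2], init[2, 1], init[2, 2] - 1,
           init[1, 3] / tscale, init[2, 3] / tscale)
  }
  h <- 1e-4
  best_q <- q; best_f <- loss(q)
  trace <- numeric(0)
  converged <- FALSE
  for (run in seq_len(optimizer$restarts + 1L)) {
    q <- best_q
    step <- optimizer$max_step
    g_prev <- NULL
    run_converged <- FALSE
    for (it in seq_len(optimizer$max_iterations)) {
      g <- vapply(seq_len(np), function(i) {
        e <- numeric(np); e[i] <- h
        (loss(q + e) - loss(q - e)) / (2 * h)
      }, numeric(1))
      gn <- sqrt(sum(g^2))
      if (gn < 1e-14) { run_converged <- TRUE; break }
      d <- g / gn
      if (!is.null(g_prev) && sum(d * g_prev) < 0)
        step <- step * optimizer$relaxation
      g_prev <- d
      q <- q - step * d
      f <- loss(q)
      trace <- c(trace, f)
      if (f < best_f) { best_f <- f; best_q <- q }
      if (step < optimizer$min_step) { run_converged <- TRUE; break }
    }
    converged <- run_converged
  }
  if (!converged)
    warning("registration did not converge; returning best transform found")
  list(affine = params_to_affine(expand(best_q), tscale),
       final_msd = best_f, converged = converged, trace = trace)
}

#' Registration pipeline record
#'
#' Bundles the ordered operations that map a high-resolution cube onto the
#' fixed low-resolution grid: orientation (quarter turns then flips),
#' resize target and interpolation, and the optimised 2-D affine.
#'
#' @param rot90_quarter_turns,flip_axes Orientation applied first.
#' @param target_shape Shape of the fixed (low-resolution) grid.
#' @param affine 3x3 homogeneous transform (fixed -> resized-moving
#'   coordinates, center origin); identity by default.
#' @param interpolation Resize kernel.
#' @param final_msd Mean square difference achieved on the target images.
#' @return An object of class `reg_pipeline`.
#' @export
reg_pipeline <- function(rot90_quarter_turns = 0L, flip_axes = character(),
                         target_shape, affine = diag(3),
                         interpolation = "bicubic", final_msd = NA_real_) {
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  if (any(target_shape < 1L)) stop("target shape must be positive")
  structure(list(rot90_quarter_turns = ((as.integer(rot90_quarter_turns) %% 4L) + 4L) %% 4L,
                 flip_axes = flip_axes,
                 target_shape = as.integer(target_shape),
                 affine = affine, interpolation = interpolation,
                 final_msd = final_msd),
            class = "reg_pipeline")
}

#' @export
print.reg_pipeline <- function(x, ...) {
  cat(sprintf("<reg_pipeline> rot90 x%d, flips [%s], target %dx%d (%s), final MSD %.3g\n",
              x$rot90_quarter_turns, paste(x$flip_axes, collapse = ","),
              x$target_shape[1], x$target_shape[2], x$interpolation, x$final_msd))
  invisible(x)
}

#' Apply a registration pipeline to a single image
#'
#' @param img Numeric matrix.
#' @param pipeline A [reg_pipeline()].
#' @param fill Fill value for out-of-view pixels.
#' @return Matrix on the fixed grid with a `"valid"` attribute.
#' @export
apply_pipeline_image <- function(img, pipeline, fill = 0) {
  r <- orient_and_resize(img, pipeline$rot90_quarter_turns, pipeline$flip_axes,
                         pipeline$target_shape, pipeline$interpolation)
  warp_affine(r, pipeline$affine, out_shape = pipeline$target_shape, fill = fill)
}

#' Apply a registration pipeline to every band of a cube
#'
#' Each band slice is independently oriented, resized and affine-warped
#' onto the fixed grid; the spectral axis is unchanged and pixels that fall
#' outside the moving cube's view are flagged in the bad-pixel mask.
#'
#' @param cube A [chem_cube()] (the moving, high-resolution cube).
#' @param pipeline A [reg_pipeline()].
#' @param fixed_pixel_size_um Pixel size of the fixed grid to stamp on the
#'   result (defaults to scaling the moving pixel size by the resize ratio).
#' @return A registered [chem_cube()] on the fixed grid.
#' @export
apply_registration <- function(cube, pipeline, fixed_pixel_size_um = NULL) {
  stopifnot(inherits(cube, "chem_cube"), inherits(pipeline, "reg_pipeline"))
  nb <- dim(cube$data)[3]
  out <- array(0, dim = c(pipeline$target_shape, nb))
  valid <- matrix(TRUE, pipeline$target_shape[1], pipeline$target_shape[2])
  for (b in seq_len(nb)) {
    w <- apply_pipeline_image(cube$data[, , b], pipeline, fill = 0)
    out[, , b] <- w
    valid <- valid & attr(w, "valid")
  }
  if (is.null(fixed_pixel_size_um)) {
    osh <- if (pipeline$rot90_quarter_turns %% 2L == 1L)
      rev(dim(cube$data)[1:2]) else dim(cube$data)[1:2]
    fixed_pixel_size_um <- cube$pixel_size_um * osh / pipeline$target_shape
  }
  chem_cube(out, cube$axis, pixel_size_um = fixed_pixel_size_um,
            bad_pixel_mask = !valid, modality = cube$modality)
}

#' Register a high-resolution cube onto a low-resolution cube's grid
#'
#' The full five-step multivariate registration: PCA on each cube, selected
#' PC score images (optionally thresholded into binary masks) as targets,
#' orientation and bicubic down-sampling of the high-resolution target,
#' affine optimisation, and slice-wise application to the whole cube.
#' Which PC carries the salient common feature differs per modality (for a
#' blend-type sample, PC 1 of one modality and PC 2 of the other may show
#' the same loop feature); the defaults can be overridden per cube.
#'
#' @param low,high [chem_cube()]s: the fixed low-resolution and moving
#'   high-resolution cube.
#' @param pc_low,pc_high PC score image used as registration target.
#' @param threshold `"otsu"` (binary masks) or `"none"` (grayscale targets,
#'   useful when thresholding degrades the feature).
#' @param rot90_quarter_turns,flip_axes Orientation hints for the moving
#'   image; with `search_orientation = TRUE` all 8 dihedral orientations
#'   are tried and scored by post-registration MSD.
#' @param search_orientation Exhaustive dihedral orientation search.
#' @param optimizer Settings from [regular_step_optimizer()].
#' @param dof Degrees of freedom for [register_affine()]; the affine stage
#'   is initialised from a similarity-stage fit.
#' @param smooth_sigma Gaussian sigma (pixels) applied to both target
#'   images before optimisation (0 disables); widens the capture range of
#'   the mean-square metric on binary masks.
#' @return List: `registered` (the high cube on the low grid) and
#'   `pipeline` (a [reg_pipeline()] for reuse).
#' @export
register_cubes <- function(low, high, pc_low = 1L, pc_high = 1L,
                           threshold = c("otsu", "none"),
                           rot90_quarter_turns = 0L, flip_axes = character(),
                           search_orientation = FALSE,
                           optimizer = regular_step_optimizer(),
                           dof = c("affine", "similarity"),
                           smooth_sigma = 1) {
  threshold <- match.arg(threshold)
  dof <- match.arg(dof)
  stopifnot(inherits(low, "chem_cube"), inherits(high, "chem_cube"))
  target_of <- function(cube, pc) {
    p <- cube_pca(unfold(cube), pc)
    img <- score_image(p, pc)
    img[!is.finite(img)] <- 0
    img
  }
  t_low <- target_of(low, pc_low)
  t_high <- target_of(high, pc_high)
  if (threshold == "otsu") {
    mask_auto <- function(img) {
      m <- threshold_mask(img, "otsu")
      # polarity: the salient feature is taken as the minority phase
      if (mean(m) > 0.5) m <- !m
      m * 1.0
    }
    t_low <- mask_auto(t_low)
    t_high <- mask_auto(t_high)
  }
  fixed_shape <- dim(low$data)[1:2]
  # slight smoothing widens the capture range of the mean-square metric
  t_low_s <- gaussian_blur(t_low, smooth_sigma)
  orientations <- if (search_orientation) {
    expand.grid(k = 0:3, fh = c(FALSE, TRUE), stringsAsFactors = FALSE)
  } else data.frame(k = rot90_quarter_turns,
                    fh = "horizontal" %in% flip_axes)
  fv <- "vertical" %in% flip_axes && !search_orientation
  two_stage <- function(fx, mv) {
    # similarity stage first (better conditioned), then the full affine
    s <- register_affine(fx, mv, optimizer, dof = "similarity")
    if (dof == "similarity") return(s)
    register_affine(fx, mv, optimizer, dof = "affine", init = s$affine)
  }
  best <- NULL
  for (i in seq_len(nrow(orientations))) {
    flips <- c(if (fv) "vertical", if (orientations$fh[i]) "horizontal")
    cand <- gaussian_blur(orient_and_resize(t_high, orientations$k[i], flips,
                                            fixed_shape), smooth_sigma)
    fit <- tryCatch(suppressWarnings(two_stage(t_low_s, cand)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$final_msd < best$fit$final_msd)
      best <- list(k = orientations$k[i], flips = flips, fit = fit)
  }
  if (is.null(best)) stop("registration failed for every candidate orientation; ",
                          "try different PCs or orientation hints")
  if (threshold == "otsu") {
    ml <- t_low > 0.5
    mh <- apply_pipeline_image(orient_and_resize(t_high, best$k, best$flips,
                                                 fixed_shape),
                               reg_pipeline(0L, character(), fixed_shape,
                                            best$fit$affine)) > 0.5
    if (!any(ml & mh))
      stop("registered masks have zero overlap; try a different PC or orientation")
  }
  pipe <- reg_pipeline(best$k, best$flips, fixed_shape, best$fit$affine,
                       final_msd = best$fit$final_msd)
  list(registered = apply_registration(high, pipe,
                                       fixed_pixel_size_um = low$pixel_size_um),
       pipeline = pipe)
}

#' Serialise a registration pipeline to JSON
#'
#' @param pipeline A [reg_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pipeline <- function(pipeline, path) {
  jsonlite::write_json(list(rot90_quarter_turns = pipeline$rot90_quarter_turns,
                            flip_axes = pipeline$flip_axes,
                            target_shape = pipeline$target_shape,
                            interpolation = pipeline$interpolation,
                            affine = pipeline$affine,  # row-major 3x3
                            final_msd = pipeline$final_msd),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a registration pipeline from JSON
#'
#' @param path JSON path written by [write_pipeline()].
#' @return A [reg_pipeline()].
#' @export
read_pipeline <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- if (is.matrix(x$affine)) x$affine
       else matrix(unlist(x$affine), 3L, 3L, byrow = TRUE)
  reg_pipeline(x$rot90_quarter_turns, as.character(x$flip_axes),
               x$target_shape, A, x$interpolation, x$final_msd)
}
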