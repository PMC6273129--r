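# Synthetic paired-modality phantom generator. Produces two chemical image
# cubes that share latent concentration maps (linear mixing of per-class
# pure spectra built from Gaussian peaks), with a known class map, a known
# misalignment of the high-resolution cube (quarter turns, flips, the
# high/low pixel-size ratio and an affine jitter), optional modality-
# private structure, noise and bad pixels — ground truth for every
# pipeline stage without any external data.

#' Evaluate a sum of Gaussian peaks on a spectral axis
#'
#' @param axis A [spectral_axis()].
#' @param peaks Data frame with columns `center`, `width` (Gaussian sigma,
#'   same unit as the axis) and `amplitude`.
#' @return Numeric vector along the axis.
#' @export
pure_spectrum <- function(axis, peaks) {
  stopifnot(inherits(axis, "spectral_axis"), is.data.frame(peaks))
  if (any(peaks$width <= 0)) stop("peak widths must be positive")
  rng <- range(axis$values)
  if (any(peaks$center < rng[1] | peaks$center > rng[2]))
    stop("peak centers must lie within the axis range")
  v <- numeric(length(axis$values))
  for (i in seq_len(nrow(peaks)))
    v <- v + peaks$amplitude[i] *
      exp(-(axis$values - peaks$center[i])^2 / (2 * peaks$width[i]^2))
  v
}

# separable Gaussian blur with replicate edges
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(n) {
    W <- matrix(0, n, n)
    for (t in -half:half) {
      j <- pmin(pmax(seq_len(n) + t, 1L), n)
      W[cbind(seq_len(n), j)] <- W[cbind(seq_len(n), j)] + k[t + half + 1L]
    }
    W
  }
  blur1(nrow(m)) %*% m %*% t(blur1(ncol(m)))
}

smooth_random_field <- function(shape, sigma = 6) {
  f <- gaussian_blur(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]), sigma)
  rng <- range(f)
  if (diff(rng) == 0) return(matrix(0.5, shape[1], shape[2]))
  (f - rng[1]) / diff(rng)
}

# default peak tables: three classes, modality-specific band positions
default_peaks_a <- function() list(
  data.frame(center = c(1080, 1500), width = c(30, 40), amplitude = c(1.0, 0.5)),
  data.frame(center = c(1180, 1620), width = c(25, 35), amplitude = c(0.9, 0.6)),
  data.frame(center = c(1320, 1730), width = c(28, 30), amplitude = c(1.0, 0.7)))
default_peaks_b <- function() list(
  data.frame(center = c(520),        width = c(30),     amplitude = c(1.2)),
  data.frame(center = c(950, 1600),  width = c(35, 40), amplitude = c(1.0, 0.4)),
  data.frame(center = c(1250),       width = c(30),     amplitude = c(1.1)))

#' Specification of a paired-modality phantom
#'
#' Defaults emulate the geometry of a drop-cast polymer blend imaged at
#' 25 um (low-resolution modality A, IR-like, 120 bands) and 6.2 um
#' (high-resolution modality B, Raman-like, 60 bands): a salient annulus
#' ("loop") feature, a central disk plus inclusions, smooth background
#' texture, a quarter-turn + horizontal-flip orientation mismatch and a
#' small affine jitter.
#'
#' @param lr_shape Low-resolution grid `(rows, cols)`.
#' @param pixel_size_lr_um,pixel_size_hr_um Pixel sizes; their ratio sets
#'   the high-resolution grid (not a whole-number multiple by default).
#' @param axis_a,axis_b Spectral axes of the two modalities.
#' @param peaks_a,peaks_b Per-class peak tables (lists of data frames).
#' @param shared_weights Per-class weight in `[0, 1]`: 1 means the class
#'   concentration map is identical in both modalities, 0 means modality B
#'   sees an independent map for that class.
#' @param confusable Optional list `(a =, b =)` of class-index pairs whose
#'   pure spectra are made identical within that modality, creating
#'   complementary information across modalities.
#' @param rot90_quarter_turns,flip_axes Orientation mismatch of the
#'   high-resolution cube.
#' @param rotation_deg,scale,shear,translation_px Affine jitter of the
#'   high-resolution cube (translation in high-resolution pixels).
#' @param noise_sd Gaussian noise sigma per modality `(a, b)`, on the scale
#'   of unit peak amplitudes.
#' @param stripe_sd Optional per-row stripe noise sigma (linear-array
#'   artefact emulation), per modality.
#' @param n_bad_pixels Dead/spike pixels injected per modality.
#' @param texture Amplitude of smooth within-class concentration texture.
#' @param seed RNG seed; the same seed reproduces the phantom bit-for-bit.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(lr_shape = c(48L, 46L),
                         pixel_size_lr_um = 25, pixel_size_hr_um = 6.2,
                         axis_a = spectral_axis(seq(1000, 1800, length.out = 120),
                                                "wavenumber", "IR"),
                         axis_b = spectral_axis(seq(400, 1800, length.out = 60),
                                                "raman_shift", "Raman"),
                         peaks_a = default_peaks_a(),
                         peaks_b = default_peaks_b(),
                         shared_weights = c(1, 1, 1),
                         confusable = NULL,
                         rot90_quarter_turns = 1L,
                         flip_axes = "horizontal",
                         rotation_deg = 3, scale = 1, shear = 0,
                         translation_px = c(2, -2),
                         noise_sd = c(a = 0.01, b = 0.01),
                         stripe_sd = c(a = 0, b = 0),
                         n_bad_pixels = c(a = 0, b = 0),
                         texture = 0.15, seed = 1L) {
  n_classes <- length(peaks_a)
  stopifnot(length(peaks_b) == n_classes,
            length(shared_weights) == n_classes,
            all(shared_weights >= 0 & shared_weights <= 1))
  ratio <- pixel_size_lr_um / pixel_size_hr_um
  if (ratio < 1) stop("the low-resolution pixel must be larger than the high-resolution one")
  hr_shape <- as.integer(round(lr_shape * ratio))
  structure(list(lr_shape = as.integer(lr_shape), hr_shape = hr_shape,
                 pixel_size_lr_um = pixel_size_lr_um,
                 pixel_size_hr_um = pixel_size_hr_um,
                 axis_a = axis_a, axis_b = axis_b,
                 peaks_a = peaks_a, peaks_b = peaks_b,
                 n_classes = n_classes,
                 shared_weights = shared_weights, confusable = confusable,
                 rot90_quarter_turns = as.integer(rot90_quarter_turns),
                 flip_axes = flip_axes,
                 rotation_deg = rotation_deg, scale = scale, shear = shear,
                 translation_px = translation_px,
                 noise_sd = noise_sd, stripe_sd = stripe_sd,
                 n_bad_pixels = n_bad_pixels,
                 texture = texture, seed = as.integer(seed)),
            class = "phantom_spec")
}

# per-class concentration maps on the aligned high-resolution grid:
# background, an open elliptical loop (the salient marker feature; tilted
# and gapped so that no rotation is ambiguous), central disk + inclusions
# of unequal size; non-negative, summing to 1 at every pixel
concentration_maps <- function(shape, texture = 0.15, n_classes = 3L) {
  r <- (row(matrix(0, shape[1], shape[2])) - (shape[1] + 1) / 2) / min(shape)
  c_ <- (col(matrix(0, shape[1], shape[2])) - (shape[2] + 1) / 2) / min(shape)
  a <- 0.33; b <- 0.24; phi <- 25 * pi / 180
  u <- cos(phi) * r + sin(phi) * c_
  v <- -sin(phi) * r + cos(phi) * c_
  rad_e <- sqrt((u / a)^2 + (v / b)^2)
  ang <- atan2(v, u)
  ann <- (abs(rad_e - 1) < 0.12 & !(ang > 0.4 & ang < 1.1)) * 1
  disk <- (sqrt(r^2 + c_^2) < 0.09) * 1
  blobs <- matrix(0, shape[1], shape[2])
  for (ctr in list(c(-0.28, -0.25, 0.06), c(0.26, 0.21, 0.05),
                   c(-0.18, 0.29, 0.045), c(0.27, -0.22, 0.065)))
    blobs <- pmax(blobs, (sqrt((r - ctr[1])^2 + (c_ - ctr[2])^2) < ctr[3]) * 1)
  sig <- min(shape) / 60
  maps <- list(NULL,
               gaussian_blur(ann, sig),
               gaussian_blur(pmax(disk, blobs), sig))
  fg <- pmin(maps[[2]] + maps[[3]], 1)
  maps[[1]] <- 1 - fg
  if (texture > 0)
    maps <- lapply(maps, function(m)
      pmax(m + texture * (smooth_random_field(shape, min(shape) / 10) - 0.5) *
             (m > 0.02), 0))
  tot <- Reduce(`+`, maps)
  tot[tot == 0] <- 1
  lapply(maps[seq_len(n_classes)], function(m) m / tot)
}

mix_cube <- function(maps, spectra_matrix) {
  # maps: list of matrices; spectra_matrix: classes x bands
  shape <- dim(maps[[1]])
  C <- vapply(maps, as.vector, numeric(prod(shape)))  # row-major? column-major
  vals <- C %*% spectra_matrix
  array(vals, dim = c(shape, ncol(spectra_matrix)))
}

add_noise <- function(arr, sd, stripe_sd = 0) {
  if (sd > 0) arr <- arr + array(stats::rnorm(length(arr), sd = sd), dim = dim(arr))
  if (stripe_sd > 0) {
    stripes <- stats::rnorm(dim(arr)[1], sd = stripe_sd)
    arr <- arr + array(rep(stripes, times = prod(dim(arr)[2:3])), dim = dim(arr))
  }
  arr
}

inject_bad_pixels <- function(arr, n) {
  if (n < 1) return(list(arr = arr, idx = cbind(integer(0), integer(0))))
  d <- dim(arr)
  idx <- cbind(sample.int(d[1], n, replace = TRUE),
               sample.int(d[2], n, replace = TRUE))
  idx <- idx[!duplicated(idx), , drop = FALSE]
  mx <- max(abs(arr))
  for (i in seq_len(nrow(idx)))
    arr[idx[i, 1], idx[i, 2], ] <- if (i %% 2L == 0L) 0 else 50 * mx
  list(arr = arr, idx = idx)
}

jitter_affine <- function(spec) {
  th <- spec$rotation_deg * pi / 180
  L <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE) %*%
    matrix(c(spec$scale, spec$shear, 0, spec$scale), 2, 2, byrow = TRUE)
  A <- diag(3)
  A[1:2, 1:2] <- L
  A[1:2, 3] <- spec$translation_px
  A
}

#' Generate a paired-modality phantom with ground truth
#'
#' Builds the noiseless aligned scene (concentration maps x pure spectra on
#' the high-resolution grid), derives the low-resolution modality-A cube by
#' antialiased bicubic down-sampling, derives the misaligned high-resolution
#' modality-B cube by affine jitter followed by the inverse orientation
#' operations, and adds noise and bad pixels last. The returned truth holds
#' the class maps, the exact registration pipeline that undoes the
#' misalignment, landmark points, the pure spectra and the noiseless cubes.
#' The same seed yields bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `a_lr` (low-resolution modality A),
#'   `b_hr_misaligned` (high-resolution modality B to be registered),
#'   `b_lr` (ideally registered modality B on the low-resolution grid, for
#'   fusion work that assumes registration), and `truth` (class maps,
#'   pipeline, landmarks, concentration maps, spectra, noiseless cubes).
#' @export
make_phantom_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  hr <- spec$hr_shape; lr <- spec$lr_shape
  maps_a <- concentration_maps(hr, spec$texture, spec$n_classes)
  maps_b <- maps_a
  for (j in seq_len(spec$n_classes)) {
    w <- spec$shared_weights[j]
    if (w < 1) {
      private <- smooth_random_field(hr, min(hr) / 12)
      maps_b[[j]] <- w * maps_a[[j]] + (1 - w) * private
    }
  }
  tot_b <- Reduce(`+`, maps_b)
  maps_b <- lapply(maps_b, function(m) m / tot_b)

  spec_a <- t(vapply(spec$peaks_a, function(p) pure_spectrum(spec$axis_a, p),
                     numeric(length(spec$axis_a$values))))
  spec_b <- t(vapply(spec$peaks_b, function(p) pure_spectrum(spec$axis_b, p),
                     numeric(length(spec$axis_b$values))))
  if (!is.null(spec$confusable)) {
    if (!is.null(spec$confusable$a))
      spec_a[spec$confusable$a[2], ] <- spec_a[spec$confusable$a[1], ]
    if (!is.null(spec$confusable$b))
      spec_b[spec$confusable$b[2], ] <- spec_b[spec$confusable$b[1], ]
  }

  scene_a_hr <- mix_cube(maps_a, spec_a)
  scene_b_hr <- mix_cube(maps_b, spec_b)

  downsample_cube <- function(arr) {
    out <- array(0, dim = c(lr, dim(arr)[3]))
    for (b in seq_len(dim(arr)[3]))
      out[, , b] <- resize_image(arr[, , b], lr, "bicubic")
    out
  }
  a_lr_clean <- downsample_cube(scene_a_hr)
  b_lr_clean <- downsample_cube(scene_b_hr)

  # misalign modality B: affine jitter about the center, then the inverse
  # orientation so that (rot90, flips) followed by the recovered affine
  # restores alignment
  J <- jitter_affine(spec)
  jittered <- array(0, dim = dim(scene_b_hr))
  for (b in seq_len(dim(scene_b_hr)[3])) {
    w <- warp_affine(scene_b_hr[, , b], J, fill = 0)
    jittered[, , b] <- w
  }
  unorient <- function(img) rot90_image(flip_image(img, spec$flip_axes),
                                        -spec$rot90_quarter_turns)
  mis_shape <- dim(unorient(jittered[, , 1]))
  b_mis <- array(0, dim = c(mis_shape, dim(jittered)[3]))
  for (b in seq_len(dim(jittered)[3])) b_mis[, , b] <- unorient(jittered[, , b])

  # ground-truth pipeline affine on the low-resolution grid: conjugate the
  # inverse jitter by the per-axis resize scaling about the image center
  S <- diag(c(lr / hr, 1))
  A_truth <- S %*% solve(J) %*% solve(S)
  A_truth[3, ] <- c(0, 0, 1)
  truth_pipe <- reg_pipeline(spec$rot90_quarter_turns, spec$flip_axes, lr,
                             A_truth)

  noisy <- function(arr, m) add_noise(arr, spec$noise_sd[[m]], spec$stripe_sd[[m]])
  a_lr_n <- noisy(a_lr_clean, "a")
  b_mis_n <- noisy(b_mis, "b")
  b_lr_n <- noisy(b_lr_clean, "b")
  bp_a <- inject_bad_pixels(a_lr_n, spec$n_bad_pixels[["a"]])
  bp_b <- inject_bad_pixels(b_mis_n, spec$n_bad_pixels[["b"]])

  # argmax class maps; pixels whose dominant concentration falls below the
  # purity threshold are mixtures of classes and left unlabelled (0)
  purity <- 0.85
  label_map <- function(maps, shape) {
    conc <- simplify2array(lapply(maps, as.vector))
    cls <- max.col(conc, ties.method = "first")
    cls[conc[cbind(seq_len(nrow(conc)), cls)] < purity] <- 0L
    matrix(as.integer(cls), shape[1], shape[2])
  }
  class_hr <- label_map(maps_a, hr)
  class_lr <- label_map(lapply(maps_a, function(m) resize_image(m, lr, "bicubic")), lr)

  landmarks_lr <- cbind(row = round(lr[1] * c(0.35, 0.35, 0.65, 0.65)),
                        col = round(lr[2] * c(0.35, 0.65, 0.35, 0.65)))

  mk <- function(arr, axis, px, modality)
    chem_cube(arr, axis, pixel_size_um = px, modality = modality)
  list(
    a_lr = mk(bp_a$arr, spec$axis_a, spec$pixel_size_lr_um, spec$axis_a$modality),
    b_hr_misaligned = mk(bp_b$arr, spec$axis_b, spec$pixel_size_hr_um,
                         spec$axis_b$modality),
    b_lr = mk(b_lr_n, spec$axis_b, spec$pixel_size_lr_um, spec$axis_b$modality),
    truth = list(pipeline = truth_pipe,
                 jitter_affine = J,
                 class_lr = class_lr, class_hr = class_hr,
                 landmarks_lr = landmarks_lr,
                 maps_a_hr = maps_a, maps_b_hr = maps_b,
                 pure_spectra_a = spec_a, pure_spectra_b = spec_b,
                 a_lr_clean = mk(a_lr_clean, spec$axis_a, spec$pixel_size_lr_um,
                                 spec$axis_a$modality),
                 b_lr_clean = mk(b_lr_clean, spec$axis_b, spec$pixel_size_lr_um,
                                 spec$axis_b$modality),
                 b_hr_aligned_clean = mk(scene_b_hr, spec$axis_b,
                                         spec$pixel_size_hr_um,
                                         spec$axis_b$modality),
                 a_hr_aligned_clean = mk(scene_a_hr, spec$axis_a,
                                         spec$pixel_size_hr_um,
                                         spec$axis_a$modality),
                 bad_pixels_a = bp_a$idx, bad_pixels_b = bp_b$idx),
    spec = spec)
}

#' Generate a resolution test target (bar triplets or spot pairs)
#'
#' Emulates a USAF-style resolving-power target: a binary bar-triplet
#' pattern (or pairs of sub-resolution Gaussian spots) rendered on the
#' high-resolution grid, with the low-resolution version produced by exact
#' block averaging. Two-band spectra separate pattern from background in
#' both modalities, so the pattern is fully shared across modalities.
#'
#' @param pattern `"bars"` (triplets of parallel bars, width = gap) or
#'   `"spots"` (pairs of Gaussian spots a fixed distance apart).
#' @param bar_width_hr Bar width in high-resolution pixels (>= 1).
#' @param spot_separation_hr Center distance of each spot pair.
#' @param ratio Integer high/low resolution factor (block-average window).
#' @param hr_shape High-resolution grid; must be divisible by `ratio`.
#' @param noise_sd Gaussian noise added to both cubes.
#' @param seed RNG seed (noise only; geometry is deterministic).
#' @return List `a_lr`, `b_lr`, `a_hr`, `b_hr` ([chem_cube()]s) and
#'   `truth` (pattern images, bar/spot geometry, profile locations).
#' @export
make_resolution_target <- function(pattern = c("bars", "spots"),
                                   bar_width_hr = 3L, spot_separation_hr = 3L,
                                   ratio = 4L, hr_shape = c(64L, 64L),
                                   noise_sd = 0, seed = 1L) {
  pattern <- match.arg(pattern)
  hr_shape <- as.integer(hr_shape); ratio <- as.integer(ratio)
  if (any(hr_shape %% ratio != 0L)) stop("'hr_shape' must be divisible by 'ratio'")
  if (bar_width_hr < 1L) stop("bar width must be at least 1 high-resolution pixel")
  set.seed(seed)
  img <- matrix(0, hr_shape[1], hr_shape[2])
  truth <- list(pattern = pattern, ratio = ratio)
  if (pattern == "bars") {
    w <- as.integer(bar_width_hr)
    r0 <- as.integer(hr_shape[1] * 0.25); h <- as.integer(hr_shape[1] * 0.5)
    c0 <- as.integer(hr_shape[2] * 0.3)
    starts <- c0 + (0:2) * 2L * w
    for (s in starts) img[r0:(r0 + h), s:(s + w - 1L)] <- 1
    truth$bar_cols <- starts + (w - 1) / 2
    truth$profile_row <- r0 + h %/% 2L
    truth$bar_width <- w
  } else {
    sep <- spot_separation_hr
    ctrs <- list(c(hr_shape[1] * 0.3, hr_shape[2] * 0.35),
                 c(hr_shape[1] * 0.55, hr_shape[2] * 0.6),
                 c(hr_shape[1] * 0.75, hr_shape[2] * 0.3))
    rr <- row(img); cc <- col(img)
    pairs <- list()
    for (ct in ctrs) {
      p1 <- c(ct[1], ct[2] - sep / 2); p2 <- c(ct[1], ct[2] + sep / 2)
      img <- img + exp(-((rr - p1[1])^2 + (cc - p1[2])^2) / (2 * 0.8^2)) +
                   exp(-((rr - p2[1])^2 + (cc - p2[2])^2) / (2 * 0.8^2))
      pairs[[length(pairs) + 1L]] <- rbind(p1, p2)
    }
    truth$spot_pairs <- pairs
    truth$separation <- sep
  }
  lrs <- hr_shape %/% ratio
  block_avg <- function(m) {
    out <- matrix(0, lrs[1], lrs[2])
    for (i in seq_len(lrs[1])) for (j in seq_len(lrs[2]))
      out[i, j] <- mean(m[((i - 1L) * ratio + 1L):(i * ratio),
                          ((j - 1L) * ratio + 1L):(j * ratio)])
    out
  }
  img_lr <- block_avg(img)
  axis_a <- spectral_axis(c(1200, 1600), "wavenumber", "IR")
  axis_b <- spectral_axis(c(800, 1400), "raman_shift", "Raman")
  two_band <- function(m, lo, hi)
    array(c(lo[1] + (hi[1] - lo[1]) * m, lo[2] + (hi[2] - lo[2]) * m),
          dim = c(dim(m), 2L))
  cube_of <- function(m, axis, px, lo = c(0.1, 0.9), hi = c(1.0, 0.1)) {
    arr <- two_band(m, lo, hi)
    if (noise_sd > 0) arr <- add_noise(arr, noise_sd)
    chem_cube(arr, axis, pixel_size_um = px, modality = axis$modality)
  }
  list(a_hr = cube_of(img, axis_a, 6.2),
       b_hr = cube_of(img, axis_b, 6.2, lo = c(0.05, 0.8), hi = c(0.9, 0.2)),
       a_lr = cube_of(img_lr, axis_a, 6.2 * ratio),
       b_lr = cube_of(img_lr, axis_b, 6.2 * ratio, lo = c(0.05, 0.8),
                      hi = c(0.9, 0.2)),
       truth = c(truth, list(img_hr = img, img_lr = img_lr)))
}
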