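# shared fixture builders: everything is generated in code at test time

# wrap a plain matrix as an unfolded object (n = r * c pixels)
as_unfolded <- function(m, shape = NULL, axis = NULL) {
  n <- nrow(m)
  if (is.null(shape)) shape <- c(n, 1L)
  if (is.null(axis)) {
    axis <- if (ncol(m) >= 2L)
      spectral_axis(seq_len(ncol(m)) + 999, "wavenumber")
    else chemfuse:::index_axis(ncol(m))
  }
  structure(list(values = m,
                 index_map = cbind(row = rep(seq_len(shape[1]), each = shape[2]),
                                   col = rep(seq_len(shape[2]), times = shape[1])),
                 shape = as.integer(shape), axis = axis,
                 pixel_size_um = c(1, 1), modality = axis$modality),
            class = "unfolded")
}

random_cube <- function(r = 5, c = 4, b = 6, seed = 1) {
  set.seed(seed)
  chem_cube(array(stats::rnorm(r * c * b), c(r, c, b)),
            spectral_axis(seq(1000, 1600, length.out = b), "wavenumber", "IR"),
            pixel_size_um = 25)
}

# balanced 3-class Gaussian spectra for null/permutation experiments
balanced_classes <- function(n_per = 60, bands = 10, sep = 4, seed = 1) {
  set.seed(seed)
  mu <- matrix(stats::rnorm(3 * bands), 3, bands) * sep
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(stats::rnorm(n_per * bands), n_per, bands), 2L, mu[k, ], "+")))
  list(X = X, labels = rep(1:3, each = n_per))
}

# landmark disagreement (in low-resolution pixels) between a recovered and
# the ground-truth registration pipeline, evaluated by pushing coordinate
# ramp images through both (bilinear interpolation is exact on ramps)
landmark_error <- function(ph, pipeline) {
  d <- dim(ph$b_hr_misaligned$data)[1:2]
  ramp <- array(0, c(d, 2))
  ramp[, , 1] <- row(matrix(0, d[1], d[2]))
  ramp[, , 2] <- col(matrix(0, d[1], d[2]))
  rc <- chem_cube(ramp, spectral_axis(1:2), ph$spec$pixel_size_hr_um)
  m_rec <- apply_registration(rc, pipeline)
  m_tru <- apply_registration(rc, ph$truth$pipeline)
  L <- ph$truth$landmarks_lr
  ratio <- ph$spec$pixel_size_lr_um / ph$spec$pixel_size_hr_um
  sqrt((m_rec$data[, , 1][L] - m_tru$data[, , 1][L])^2 +
       (m_rec$data[, , 2][L] - m_tru$data[, , 2][L])^2) / ratio
}

# count strict interior local maxima of a 1-d profile
n_local_maxima <- function(p, eps = 1e-9) {
  d <- diff(p)
  sum(d[-length(d)] > eps & d[-1] < -eps)
}
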