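# cube data model, unfolding, preprocessing, scaling and PCA

test_that("unfold orders pixels row-major and refold inverts it exactly", {
  cube <- chem_cube(array(as.numeric(1:12), c(2, 2, 3)), spectral_axis(1:3), 1)
  um <- unfold(cube)
  expect_equal(dim(um$values), c(4L, 3L))
  # pixel (r = 2, c = 1) -> matrix row 3
  expect_equal(unname(um$index_map[3, ]), c(2L, 1L))
  expect_identical(refold(um)$data, cube$data)

  big <- random_cube(7, 5, 4, seed = 2)
  expect_identical(refold(unfold(big))$data, big$data)
})

test_that("unfold can exclude bad pixels and refold restores them as fill", {
  cube <- random_cube(2, 2, 3, seed = 3)
  cube$bad_pixel_mask[1, 2] <- TRUE
  um <- unfold(cube, exclude_bad = TRUE)
  expect_equal(nrow(um$values), 3L)
  expect_false(any(um$index_map[, 1] == 1L & um$index_map[, 2] == 2L))
  back <- refold(um, fill = NaN)
  expect_true(is.nan(back$data[1, 2, 1]))
  expect_true(back$bad_pixel_mask[1, 2])
  expect_equal(back$data[2, 2, ], cube$data[2, 2, ])
})

test_that("refold handles single-band matrices and shape mismatches", {
  cube <- random_cube(3, 4, 2, seed = 4)
  um <- unfold(cube)
  um$values <- um$values[, 1, drop = FALSE]
  um$axis <- chemfuse:::axis_subset(um$axis, 1)
  out <- refold(um)
  expect_equal(dim(out$data), c(3L, 4L, 1L))
  um$index_map[1, 1] <- 99L
  expect_error(refold(um), "exceeds")
})

test_that("spectral axis enforces monotonicity and length", {
  expect_error(spectral_axis(c(1, 1, 2)), "monotonic")
  expect_error(spectral_axis(5), "at least 2")
  expect_silent(spectral_axis(c(2000, 1500, 1000)))  # decreasing is fine
})

test_that("autoscale gives exact zero mean / unit sd and is invertible", {
  um <- as_unfolded(cbind(c(1, 2, 3), c(5, 9, 1)))
  sc <- autoscale(um)
  expect_equal(sc$matrix$values[, 1], c(-1, 0, 1))
  expect_lt(max(abs(colMeans(sc$matrix$values))), 1e-12)
  expect_lt(max(abs(apply(sc$matrix$values, 2, sd) - 1)), 1e-12)
  back <- inverse_autoscale(sc$matrix, sc$params)
  expect_lt(max(abs(back$values - um$values)), 1e-10)
  expect_error(autoscale(as_unfolded(cbind(c(1, 1, 1)))), "zero variance")
})

test_that("block scaling equalises block sums of squares and max scaling is idempotent", {
  set.seed(5)
  b1 <- autoscale(as_unfolded(matrix(rnorm(30 * 20), 30, 20)))$matrix
  b2 <- autoscale(as_unfolded(matrix(rnorm(30 * 5), 30, 5)))$matrix
  sc <- block_and_max_scale(list(b1, b2))
  # after block scaling both had total SS == n - 1; max scaling divides each
  # block by one constant, so the SS ratio equals the squared max ratio
  ss <- vapply(sc$blocks, function(b) sum(b$values^2), numeric(1))
  expect_equal(ss[1] * sc$params$max_abs[1]^2, ss[2] * sc$params$max_abs[2]^2,
               tolerance = 1e-10)
  expect_equal(vapply(sc$blocks, function(b) max(abs(b$values)), numeric(1)),
               c(1, 1))
  # with single-band blocks the sqrt(bands) weight is 1, so the operation
  # reduces to pure maximum scaling, which is idempotent
  s1 <- block_and_max_scale(list(as_unfolded(cbind(rnorm(10))),
                                 as_unfolded(cbind(rnorm(10)))))
  s2 <- block_and_max_scale(s1$blocks)
  expect_equal(s2$blocks[[1]]$values, s1$blocks[[1]]$values)
  expect_equal(s2$blocks[[2]]$values, s1$blocks[[2]]$values)
  expect_error(block_and_max_scale(list()), "length")
})

test_that("Savitzky-Golay second derivative is exact on polynomials and trims edges", {
  nb <- 41
  um_q <- as_unfolded(matrix((1:nb)^2, 1, nb))
  d2 <- savgol_second_derivative(um_q, window = 15, polyorder = 3)
  expect_equal(ncol(d2$values), nb - 14L)
  expect_lt(max(abs(d2$values - 2)), 1e-10)
  expect_equal(length(d2$axis$values), nb - 14L)

  um_l <- as_unfolded(matrix(3 * (1:nb) + 7, 1, nb))
  expect_lt(max(abs(savgol_second_derivative(um_l, 15, 3)$values)), 1e-10)

  expect_error(savgol_second_derivative(as_unfolded(matrix(1:9, 1, 9)), 15, 3),
               "window")
})

test_that("Savitzky-Golay matches a windowed polynomial-fit oracle on a sine", {
  nb <- 60
  x <- sin((1:nb) / 5)
  um <- as_unfolded(matrix(x, 1, nb))
  got <- savgol_second_derivative(um, window = 11, polyorder = 3)$values[1, ]
  oracle <- vapply(6:(nb - 5), function(i) {
    w <- (i - 5):(i + 5)
    fit <- lm(y ~ poly(t, 3, raw = TRUE), data.frame(y = x[w], t = w - i))
    2 * coef(fit)[[3]]     # f''(0) of the local cubic
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), 1e-10)
})

test_that("bad-pixel detection flags spikes and dead pixels, not clean data", {
  # smooth scene: two smooth abundance fields mixing two band shapes
  set.seed(64)
  ax <- spectral_axis(seq(1000, 1600, length.out = 40))
  f1 <- chemfuse:::smooth_random_field(c(30, 28), 10)
  f2 <- chemfuse:::smooth_random_field(c(30, 28), 12)
  s1 <- pure_spectrum(ax, data.frame(center = 1200, width = 40, amplitude = 1))
  s2 <- pure_spectrum(ax, data.frame(center = 1450, width = 50, amplitude = 0.8))
  arr <- array(outer(as.vector(f1), s1) + outer(as.vector(f2), s2), c(30, 28, 40))
  arr <- arr + array(rnorm(length(arr), sd = 0.01), dim(arr))
  clean <- chem_cube(arr, ax, 25)
  expect_equal(sum(detect_bad_pixels(clean, 5)), 0L)

  spiked <- clean
  spiked$data[10, 12, ] <- 50 * max(clean$data)
  mask <- detect_bad_pixels(spiked, 5)
  expect_true(mask[10, 12])
  expect_equal(sum(mask), 1L)

  dead <- clean
  dead$data[3, 3, ] <- 0.123
  expect_true(detect_bad_pixels(dead, 5)[3, 3])

  flat <- chem_cube(array(1, c(4, 4, 3)), spectral_axis(1:3), 1)
  expect_warning(m <- detect_bad_pixels(flat, 5), "constant")
  expect_false(any(m))
})

test_that("PCA matches a dense eigendecomposition oracle and is orthonormal", {
  set.seed(6)
  m <- matrix(rnorm(20 * 6), 20, 6)
  um <- as_unfolded(m)
  p <- cube_pca(um, 6)
  expect_lt(max(abs(crossprod(p$loadings) - diag(6))), 1e-10)
  ev_oracle <- sort(eigen(cov(m), symmetric = TRUE)$values, decreasing = TRUE)
  expect_lt(max(abs(p$eigenvalues - ev_oracle)), 1e-8)
  # deterministic sign: the largest loading element of each component > 0
  for (j in 1:6) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("rank-1 data loads entirely on the first component", {
  s <- outer(rnorm(15), rnorm(4))
  p <- cube_pca(as_unfolded(s + 10), 3)
  expect_gt(p$explained[1], 1 - 1e-12)
  expect_lt(sum(p$explained[-1]), 1e-12)
})

test_that("PCA denoising reproduces full-rank input and shrinks noise", {
  cube <- random_cube(6, 5, 4, seed = 7)
  expect_lt(max(abs(pca_denoise(cube, 4)$data - cube$data)), 1e-10)

  set.seed(8)
  scores <- matrix(rnorm(30 * 2), 30, 2)
  loads <- matrix(rnorm(2 * 8), 2, 8)
  truth <- scores %*% loads
  sigma <- 0.3
  noisy <- truth + matrix(rnorm(length(truth), sd = sigma), nrow(truth))
  cube2 <- refold(as_unfolded(noisy, shape = c(6, 5)))
  den <- pca_denoise(cube2, 2)
  rms <- sqrt(mean((unfold(den)$values - truth)^2))
  expect_lt(rms, sigma)

  # reconstruction error is monotone non-increasing in the component count
  cube3 <- random_cube(8, 6, 5, seed = 9)
  errs <- vapply(1:5, function(k)
    sqrt(mean((pca_denoise(cube3, k)$data - cube3$data)^2)), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})
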