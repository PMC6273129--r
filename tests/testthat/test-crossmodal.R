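# correlation maps, cross-modality PLSR and resolution enhancement

test_that("correlation map has unit self-diagonal and transpose symmetry", {
  set.seed(40)
  a <- as_unfolded(matrix(rnorm(30 * 4), 30, 4))
  b <- as_unfolded(matrix(rnorm(30 * 3), 30, 3),
                   axis = spectral_axis(c(500, 900, 1300), "raman_shift", "R"))
  self <- correlation_map(a, a)
  expect_equal(diag(self$r), rep(1, 4))
  ab <- correlation_map(a, b)
  ba <- correlation_map(b, a)
  expect_lt(max(abs(ab$r - t(ba$r))), 1e-14)
  # anti-correlated band
  b2 <- b; b2$values[, 2] <- -a$values[, 1]
  expect_equal(correlation_map(a, b2)$r[1, 2], -1)
  expect_error(correlation_map(as_unfolded(matrix(1:4, 2, 2)),
                               as_unfolded(matrix(1:4, 2, 2))), "3 pixels")
})

test_that("correlation map matches a double-loop Pearson oracle", {
  set.seed(41)
  a <- as_unfolded(matrix(rnorm(5 * 3), 5, 3))
  b <- as_unfolded(matrix(rnorm(5 * 2), 5, 2))
  got <- correlation_map(a, b)$r
  for (i in 1:3) for (j in 1:2) {
    x <- a$values[, i]; y <- b$values[, j]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_lt(abs(got[i, j] - r), 1e-14)
  }
})

test_that("high-correlation pairs are thresholded, sorted and summarised as runs", {
  axis_a <- spectral_axis(seq(3040, 3070, by = 2), "wavenumber", "IR")
  axis_b <- spectral_axis(c(2928, 2932), "raman_shift", "R")
  r <- matrix(0.2, 16, 2)
  r[3, 1] <- 0.9; r[4, 1] <- 0.88; r[10, 2] <- -0.95
  map <- structure(list(r = r, axis_a = axis_a, axis_b = axis_b),
                   class = "corr_map")
  hp <- high_correlation_pairs(map, 0.85)
  expect_equal(nrow(hp), 3L)
  expect_equal(hp$r, c(-0.95, 0.9, 0.88))
  expect_equal(attr(hp, "ranges_a"), c("3044-3046", "3058"))
  low <- map; low$r[] <- 0.5
  expect_equal(nrow(high_correlation_pairs(low, 0.85)), 0L)
  expect_error(high_correlation_pairs(map, 1.5), "threshold")
  expect_equal(formals(high_correlation_pairs)$threshold, 0.85)
})

test_that("correlation slices use nearest-band lookup with spacing tolerance", {
  axis_a <- spectral_axis(c(3420, 3443.8, 3460), "wavenumber", "IR")
  axis_b <- spectral_axis(c(2920, 2932), "raman_shift", "R")
  map <- structure(list(r = matrix(1:6 / 10, 3, 2), axis_a = axis_a,
                        axis_b = axis_b), class = "corr_map")
  sl <- correlation_slice(map, 3444)
  expect_equal(attr(sl, "band"), 3443.8)
  expect_equal(unname(sl), c(0.2, 0.5), ignore_attr = TRUE)
  expect_error(correlation_slice(map, 3600), "tolerance")
  # stacking every slice reconstructs the map
  stacked <- t(vapply(axis_a$values, function(v)
    unname(correlation_slice(map, v)), numeric(2)))
  expect_equal(stacked, map$r)
})

test_that("PLSR recovers a noiseless linear map and refuses mismatched input", {
  set.seed(42)
  X <- matrix(rnorm(240 * 6), 240, 6)
  B <- matrix(rnorm(6 * 4), 6, 4)
  Y <- X %*% B
  model <- plsr_fit(X, Y, max_lv = 6)
  expect_true(all(model$test_r2 > 1 - 1e-6))
  pred <- plsr_predict(model, X)
  expect_lt(max(abs(pred - Y)), 1e-6)
  expect_error(plsr_predict(model, X[, 1:3]), "mismatch")
  expect_error(plsr_fit(X, Y, 0), "at least 1")
})

test_that("PLSR on independent noise has no predictive power", {
  r2 <- vapply(1:8, function(sd) {
    set.seed(sd)
    X <- matrix(rnorm(120 * 5), 120, 5)
    Y <- matrix(rnorm(120 * 2), 120, 2)
    mean(plsr_fit(X, Y, 4)$test_r2)
  }, numeric(1))
  expect_lt(max(abs(r2)), 0.25)
  expect_lt(abs(mean(r2)), 0.1)
})

test_that("shared-latent phantoms are cross-predictable almost perfectly", {
  ph <- make_phantom_pair(phantom_spec(seed = 43, noise_sd = c(a = 0, b = 0)))
  m <- plsr_fit(unfold(ph$a_lr), unfold(ph$b_lr), 10)
  expect_gt(min(m$test_r2, na.rm = TRUE), 0.99)
  # single-target prediction returns one column and refolds to an image
  pred1 <- plsr_predict(m, unfold(ph$a_lr), targets = ph$b_lr$axis$values[10])
  expect_equal(ncol(pred1$values), 1L)
  img <- refold(pred1)
  expect_equal(dim(img$data), c(dim(ph$a_lr$data)[1:2], 1L))
})

test_that("relative error spectrum implements the mean-spectrum formula", {
  ph <- make_phantom_pair(phantom_spec(seed = 44))
  cube <- ph$a_lr
  expect_equal(max(relative_error_spectrum(cube, cube)), 0)
  scaled <- cube; scaled$data <- cube$data * 1.02
  err <- relative_error_spectrum(cube, scaled)
  expect_equal(err, rep(2, length(err)), tolerance = 1e-9)
  zero <- cube; zero$data[, , 1] <- 0
  err2 <- relative_error_spectrum(zero, scaled)
  expect_true(is.na(err2[1]))
})

test_that("uncorrelated bands predict poorly while correlated bands predict well", {
  ph <- make_phantom_pair(phantom_spec(seed = 45, shared_weights = c(1, 0.6, 0),
                                       noise_sd = c(a = 0.005, b = 0.005)))
  ua <- unfold(ph$a_lr); ub <- unfold(ph$b_lr)
  m <- plsr_fit(ua, ub, 10)
  err <- relative_error_spectrum(ph$b_lr, refold(plsr_predict(m, ua)))
  best_r <- apply(abs(correlation_map(ua, ub)$r), 2, max)
  expect_gt(median(err[best_r < 0.5], na.rm = TRUE), 2)
  expect_lt(median(err[best_r > 0.95], na.rm = TRUE), 2)
  expect_gt(cor(best_r, -err, method = "spearman", use = "complete.obs"), 0.8)
})

test_that("enhancement equals plain prediction when denoising is a no-op", {
  rt <- make_resolution_target("spots", ratio = 4, noise_sd = 0, seed = 46)
  m <- plsr_fit(unfold(rt$b_lr), unfold(rt$a_lr), 2)
  enh <- enhance_resolution(m, rt$b_hr, denoise_components = 2)
  plain <- refold(plsr_predict(m, unfold(rt$b_hr)))
  expect_equal(enh$data, plain$data, tolerance = 1e-10)
  expect_error(enhance_resolution(m, rt$b_hr, denoise_components = 99), "rank")
})

test_that("sub-LR-pixel spot pairs are resolved in the enhanced image only", {
  rt <- make_resolution_target("spots", spot_separation_hr = 3, ratio = 4,
                               noise_sd = 0.002, seed = 47)
  m <- plsr_fit(unfold(rt$b_lr), unfold(rt$a_lr), 2)
  enh <- enhance_resolution(m, rt$b_hr, denoise_components = 2)
  pair <- rt$truth$spot_pairs[[1]]
  r_hr <- round(pair[1, 1])
  win <- round(pair[1, 2] - 4):round(pair[2, 2] + 4)
  expect_equal(n_local_maxima(enh$data[r_hr, win, 1]), 2L)
  lr_prof <- rt$a_lr$data[ceiling(r_hr / 4),
                          ceiling(min(win) / 4):ceiling(max(win) / 4), 1]
  expect_lte(n_local_maxima(lr_prof), 1L)
})
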