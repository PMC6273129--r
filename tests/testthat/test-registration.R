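# multivariate registration: thresholding, orientation/resize, the affine
# optimiser and the composed five-step pipeline

test_that("Otsu threshold splits a two-level image and rejects degenerate input", {
  img <- matrix(c(rep(0, 32), rep(10, 32)), 8, 8)
  m <- threshold_mask(img, "otsu")
  thr <- attr(m, "threshold")
  expect_gt(thr, 0); expect_lt(thr, 10)
  expect_equal(sum(m), 32L)
  expect_error(threshold_mask(matrix(1, 4, 4), "otsu"), "constant")
  expect_error(threshold_mask(img, "manual", manual_value = -1), "degenerate")
})

test_that("Otsu agrees with the EBImage oracle on a bimodal image", {
  skip_if_not_installed("EBImage")
  set.seed(15)
  img <- matrix(c(rnorm(300, 0.3, 0.05), rnorm(212, 0.7, 0.05)), 32, 16)
  img <- pmin(pmax(img, 0), 1)
  ours <- attr(threshold_mask(img, "otsu"), "threshold")
  ref <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  # both thresholds must induce the same foreground (they may sit at
  # different points of the empty gap between the modes)
  expect_identical(img > ours, img > ref)
})

test_that("orientation ops compose as expected and identity resize is exact", {
  img <- matrix(rnorm(48), 8, 6)
  expect_equal(rot90_image(img, 2), img[8:1, 6:1])
  expect_equal(rot90_image(rot90_image(img, 1), 1), rot90_image(img, 2))
  expect_equal(flip_image(img, c("vertical", "horizontal")), img[8:1, 6:1])
  out <- orient_and_resize(img, 0L, character(), dim(img))
  expect_lt(max(abs(out - img)), 1e-12)
})

test_that("down-sampling hits the requested target shape", {
  big <- matrix(rnorm(787 * 774), 787, 774)
  small <- orient_and_resize(big, target_shape = c(196, 190))
  expect_equal(dim(small), c(196L, 190L))
  # smooth images survive down-up resampling within interpolation tolerance
  smooth <- chemfuse:::gaussian_blur(matrix(rnorm(96 * 96), 96, 96), 6)
  down <- resize_image(smooth, c(24, 24))
  up <- resize_image(down, c(96, 96))
  expect_lt(sqrt(mean((up - smooth)^2)) / sd(smooth), 0.2)
})

test_that("mean square difference matches a loop oracle and handles masks", {
  set.seed(16)
  a <- matrix(rnorm(25), 5, 5); b <- matrix(rnorm(25), 5, 5)
  s <- 0
  for (i in 1:5) for (j in 1:5) s <- s + (a[i, j] - b[i, j])^2
  expect_lt(abs(mean_square_difference(a, b) - s / 25), 1e-14)
  expect_equal(mean_square_difference(a, a), 0)
  expect_equal(mean_square_difference(a, a + 1), 1)
  expect_error(mean_square_difference(a, b, matrix(FALSE, 5, 5)), "empty mask")
})

test_that("registering an image to itself returns the identity", {
  set.seed(17)
  img <- chemfuse:::gaussian_blur(matrix(rnorm(40 * 38), 40, 38), 2)
  fit <- register_affine(img, img)
  expect_lt(max(abs(fit$affine - diag(3))), 1e-3)
  expect_lt(fit$final_msd, 1e-8)
})

test_that("known translations and rotations are recovered to sub-pixel accuracy", {
  set.seed(18)
  img <- chemfuse:::gaussian_blur(matrix(rnorm(48 * 46), 48, 46), 2.5)
  # translation by (+3, -2): moving sampled at A_true x with A_true = shift
  A_t <- diag(3); A_t[1:2, 3] <- c(3, -2)
  moving <- warp_affine(img, solve(A_t), fill = 0)
  fit <- register_affine(img, moving)
  expect_lt(max(abs(fit$affine[1:2, 3] - c(3, -2))), 0.2)

  th <- 5 * pi / 180
  A_rs <- diag(3)
  A_rs[1:2, 1:2] <- 1.05 * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                                  byrow = TRUE)
  moving2 <- warp_affine(img, solve(A_rs), fill = 0)
  fit2 <- register_affine(img, moving2)
  pts <- rbind(c(-12, -11), c(-12, 11), c(12, -11), c(12, 11))
  errs <- apply(pts, 1, function(p)
    sqrt(sum(((fit2$affine - A_rs) %*% c(p, 1))[1:2]^2)))
  expect_lt(max(errs), 0.5)
})

test_that("registration is invariant to adding a constant to both images", {
  set.seed(19)
  img <- chemfuse:::gaussian_blur(matrix(rnorm(40 * 40), 40, 40), 2)
  A_t <- diag(3); A_t[1:2, 3] <- c(1.5, -1)
  moving <- warp_affine(img, solve(A_t), fill = 0)
  f1 <- register_affine(img, moving)
  f2 <- register_affine(img + 5, moving + 5)
  expect_equal(f1$affine, f2$affine, tolerance = 1e-6)
})

test_that("apply_registration is slice-wise and the identity pipeline is a no-op", {
  cube <- random_cube(6, 7, 3, seed = 20)
  ident <- reg_pipeline(0L, character(), c(6L, 7L))
  out <- apply_registration(cube, ident)
  expect_equal(out$data, cube$data, tolerance = 1e-12)

  pipe <- reg_pipeline(1L, "horizontal", c(5L, 5L),
                       {A <- diag(3); A[1:2, 3] <- c(0.4, -0.3); A})
  full <- apply_registration(cube, pipe)
  for (b in 1:3) {
    slice <- apply_pipeline_image(cube$data[, , b], pipe)
    expect_equal(full$data[, , b], unclass(slice), ignore_attr = TRUE)
  }
  expect_equal(dim(full$data)[1:2], c(5L, 5L))
})

test_that("register_cubes recovers a known phantom misalignment", {
  set.seed(1021)
  ph <- make_phantom_pair(phantom_spec(seed = 21,
                                       rotation_deg = runif(1, -5, 5),
                                       translation_px = runif(2, -3, 3)))
  res <- suppressWarnings(register_cubes(
    ph$a_lr, ph$b_hr_misaligned, pc_low = 1, pc_high = 1,
    rot90_quarter_turns = ph$spec$rot90_quarter_turns,
    flip_axes = ph$spec$flip_axes))
  expect_lt(max(landmark_error(ph, res$pipeline)), 0.5)
  expect_equal(dim(res$registered$data)[1:2], dim(ph$a_lr$data)[1:2])
})

test_that("registering a cube against itself yields a near-identity pipeline", {
  ph <- make_phantom_pair(phantom_spec(seed = 22))
  res <- suppressWarnings(register_cubes(ph$a_lr, ph$a_lr,
                                         rot90_quarter_turns = 0L))
  expect_lt(max(abs(res$pipeline$affine - diag(3))), 0.05)
})
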