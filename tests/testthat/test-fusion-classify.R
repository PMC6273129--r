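# fusion levels and PLS-DA pixel classification

test_that("split_halves is a deterministic midline split that keeps all classes", {
  cube <- random_cube(10, 10, 4, seed = 23)
  labels <- matrix(rep(rep(1:2, each = 5), 10), 10, 10)  # rows 1-5 vs 6-10
  halves <- split_halves(cube, labels, "vertical")
  expect_equal(dim(halves$train$cube$data)[1:2], c(10L, 5L))
  expect_equal(dim(halves$test$cube$data)[1:2], c(10L, 5L))
  # a class confined to the left half errors
  bad <- matrix(1L, 10, 10); bad[, 1:3] <- 2L
  expect_error(split_halves(cube, bad, "vertical"), "missing")
  # phantom class maps span both halves by construction
  ph <- make_phantom_pair(phantom_spec(seed = 24))
  h <- split_halves(ph$a_lr, ph$truth$class_lr)
  expect_equal(sort(unique(h$train$labels[h$train$labels > 0])), 1:3)
  expect_equal(sort(unique(h$test$labels[h$test$labels > 0])), 1:3)
})

test_that("low-level fusion concatenates scaled blocks with equal sums of squares", {
  ph <- make_phantom_pair(phantom_spec(seed = 25))
  fused <- low_level_fuse(ph$a_lr, ph$b_lr)
  ba <- dim(ph$a_lr$data)[3]; bb <- dim(ph$b_lr$data)[3]
  expect_equal(dim(fused$data)[3], ba + bb)
  expect_equal(dim(fused$data)[1:2], dim(ph$a_lr$data)[1:2])
  um <- unfold(fused)
  sc <- attr(fused, "scaling")$block_max
  ss_a <- sum(um$values[, 1:ba]^2) * sc$max_abs[1]^2
  ss_b <- sum(um$values[, (ba + 1):(ba + bb)]^2) * sc$max_abs[2]^2
  expect_equal(ss_a, ss_b, tolerance = 1e-10)
  expect_equal(as.character(fused$axis$bands$modality),
               rep(c("IR", "Raman"), c(ba, bb)))
  expect_error(low_level_fuse(ph$a_lr, ph$b_hr_misaligned), "register")
})

test_that("fusing a cube with itself does not change the classification", {
  ph <- make_phantom_pair(phantom_spec(seed = 26, noise_sd = c(a = 0, b = 0)))
  single <- classify_cube(ph$a_lr, ph$truth$class_lr, max_lv = 6)
  double <- classify_cube(low_level_fuse(ph$a_lr, ph$a_lr),
                          ph$truth$class_lr, max_lv = 6)
  expect_equal(single$accuracy, double$accuracy)
})

test_that("mid-level fusion stacks per-modality PC scores", {
  ph <- make_phantom_pair(phantom_spec(seed = 27))
  fused <- mid_level_fuse(ph$a_lr, ph$b_lr, n_pcs = c(10, 10))
  expect_equal(dim(fused$data)[3], 20L)
  pa <- cube_pca(unfold(ph$a_lr), 10)
  um <- unfold(fused)
  expect_equal(um$values[, 1:10], pa$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fused$axis$bands$pc, rep(1:10, 2))
  expect_error(mid_level_fuse(ph$a_lr, ph$b_lr, n_pcs = c(10000, 10)), "rank")
})

test_that("PLS-DA separates well-separated Gaussian classes with one LV", {
  set.seed(28)
  n <- 80
  X <- rbind(matrix(rnorm(n * 6), n, 6),
             sweep(matrix(rnorm(n * 6), n, 6), 2, rep(10, 6), "+"))
  labels <- rep(1:2, each = n)
  ord <- sample(2 * n)
  model <- plsda_fit(X[ord, ], labels[ord], max_lv = 5)
  expect_equal(model$n_lv, 1L)
  expect_equal(max(model$val_accuracy), 100)
  pred <- plsda_predict(model, X)
  expect_equal(pred$class, labels)
})

test_that("PLS-DA argmax breaks ties toward the lowest class index", {
  set.seed(29)
  bc <- balanced_classes(40, 8, sep = 3, seed = 29)
  model <- plsda_fit(bc$X, bc$labels, max_lv = 4)
  # degenerate response rows: equal responses pick class 1
  fake <- matrix(c(0.5, 0.5, 0), 1, 3)
  expect_equal(which.max(fake[1, ]), max.col(fake, ties.method = "first"))
  expect_error(plsda_fit(bc$X, rep(1L, nrow(bc$X)), 3), "2 classes")
  expect_error(plsda_fit(bc$X, bc$labels, 0), "at least 1")
})

test_that("training accuracy at the selected LV is perfect on separable phantoms", {
  ph <- make_phantom_pair(phantom_spec(seed = 30, noise_sd = c(a = 0, b = 0)))
  halves <- split_halves(ph$a_lr, ph$truth$class_lr)
  um <- unfold(halves$train$cube)
  lab <- halves$train$labels[um$index_map]
  model <- plsda_fit(um, lab, max_lv = 6)
  pred <- plsda_predict(model, um$values[lab > 0, ])
  expect_equal(mean(pred$class == lab[lab > 0]), 1)
})

test_that("consensus fusion marks exactly the disagreement set as unknown", {
  set.seed(31)
  a <- matrix(sample(1:3, 100, replace = TRUE), 10, 10)
  b <- a
  flip <- sample(100, 23)
  b[flip] <- (b[flip] %% 3L) + 1L
  cons <- consensus_fuse(a, b)
  expect_equal(which(cons == 0L), sort(flip))
  expect_equal(cons[-flip], a[-flip])
  expect_identical(consensus_fuse(a, a), a)
  expect_error(consensus_fuse(a, matrix(1L, 2, 2)), "shape")
})

test_that("classification accuracy follows the unknown-is-wrong rule", {
  truth <- matrix(c(rep(1L, 40), rep(2L, 40), rep(0L, 20)), 10, 10)
  expect_equal(classification_accuracy(truth, truth), 100)
  half_wrong <- truth
  half_wrong[1:20] <- 3L - half_wrong[1:20]    # flips 1<->2 on 20 labelled px
  expect_equal(classification_accuracy(half_wrong, truth), 100 * 60 / 80)
  tenth_unknown <- truth
  tenth_unknown[truth == 1L][1:8] <- 0L        # 10% of labelled set unknown
  expect_equal(classification_accuracy(tenth_unknown, truth), 90)
  expect_error(classification_accuracy(truth, matrix(0L, 10, 10)), "labelled")
  # invariant to a consistent class relabelling
  perm <- c(2L, 3L, 1L)
  relab <- function(m) { out <- m; out[m > 0] <- perm[m[m > 0]]; out }
  expect_equal(classification_accuracy(half_wrong, truth),
               classification_accuracy(relab(half_wrong), relab(truth)))
})

test_that("consensus accuracy is bounded by the disagreement rate", {
  ph <- make_phantom_pair(phantom_spec(seed = 32, noise_sd = c(a = 0.05, b = 0.05),
                                       confusable = list(a = c(2, 3), b = c(1, 2))))
  ca <- classify_cube(ph$a_lr, ph$truth$class_lr, 6)
  cb <- classify_cube(ph$b_lr, ph$truth$class_lr, 6)
  cons <- consensus_fuse(ca$class_map, cb$class_map)
  acc <- classification_accuracy(cons, ca$truth)
  disagree <- 100 * sum(ca$class_map != cb$class_map & ca$truth != 0) /
    sum(ca$truth != 0)
  expect_lte(acc, 100 - disagree + 1e-9)
})
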