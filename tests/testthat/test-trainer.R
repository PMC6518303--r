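# SGD configuration, channel replication, class-balance arithmetic,
# augmentation determinism, layer freezing and the training loop itself.

test_that("learning-rate schedule is the exact stepped decay", {
  cfg <- train_config()
  expect_identical(lr_schedule(cfg, 1), 0.001)
  expect_identical(lr_schedule(cfg, 10), 0.001)
  expect_identical(lr_schedule(cfg, 11), 0.001 * 0.1)
  expect_identical(lr_schedule(cfg, 21), 0.001 * 0.1^2)
  cfg2 <- train_config(learning_rate = 0.05, lr_drop_factor = 0.5,
                       lr_drop_period = 3)
  expect_equal(vapply(1:7, lr_schedule, numeric(1), config = cfg2),
               0.05 * 0.5^floor((1:7 - 1) / 3))
  expect_error(train_config(momentum = -1), "negative")
  expect_error(train_config(fine_tune_fraction = 0), "fine_tune_fraction")
})

test_that("grayscale replication copies channel 1 into channels 2 and 3", {
  g <- matrix(runif(12), 3, 4)
  x <- gray_to_3channel(g)
  expect_equal(dim(x), c(3L, 4L, 3L))
  expect_identical(x[, , 1], g)
  expect_identical(x[, , 2], g)
  expect_identical(x[, , 3], g)
  expect_identical(gray_to_3channel(array(g, c(3, 4, 1)))[, , 2], g)
  rgb <- array(runif(24), c(2, 4, 3))
  expect_identical(gray_to_3channel(rgb), rgb)
  z <- gray_to_3channel(matrix(0, 4, 4))
  expect_true(all(z == 0))
  expect_error(gray_to_3channel(array(0, c(2, 2, 2))), "channel")
  expect_error(gray_to_3channel(array(0, c(2, 2, 4))), "channel")
})

test_that("class-balance arithmetic reproduces the published imbalance rows", {
  # (original, augmented, ratio%) for every under-represented class
  rows <- list(c(161, 339, 67.8), c(169, 331, 66.2), c(455, 45, 9),
               c(75, 425, 85), c(400, 100, 20), c(175, 325, 65),
               c(487, 13, 2.6), c(238, 262, 52.4), c(72, 428, 85.6))
  for (r in rows) {
    got <- balance_class(r[1], 500)
    expect_equal(got$augmented_needed, r[2])
    expect_equal(got$imbalance_ratio, r[3])
  }
  expect_equal(balance_class(500, 500),
               list(augmented_needed = 0L, imbalance_ratio = 0))
  expect_error(balance_class(600, 500), "downsampling")
  expect_error(balance_class(0, 500), "original_count")
})

test_that("augmentation is deterministic and identity at zero magnitude", {
  img <- synth_batch(K = 2, n = 1)$x[, , , 1]
  pol0 <- augmentation_policy(max_translation = 0, max_rotation = 0,
                              crop_fraction_range = c(1, 1), seed = 4)
  expect_identical(augment_image(img, pol0, draw = 1), img)
  pol <- augmentation_policy(seed = 4)
  a1 <- augment_image(img, pol, draw = 3)
  a2 <- augment_image(img, pol, draw = 3)
  a3 <- augment_image(img, pol, draw = 4)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
  expect_equal(dim(a1), dim(img))
  expect_error(augmentation_policy(crop_fraction_range = c(0.5, 1.2)),
               "crop_fraction_range")
})

test_that("a 90-degree rotation equals the quarter-turn index permutation", {
  img <- synth_batch(K = 2, n = 1, side = 32)$x[, , , 1]
  got <- cbmir:::affine_image(img, angle = 90)
  for (c in 1:3) {
    want <- t(img[, , c])[ncol(img[, , c]):1, ]  # independent permutation
    expect_equal(got[, , c], want, tolerance = 1e-12)
  }
})

test_that("balancing tops up small classes to the target with augmentations", {
  b <- synth_batch(K = 2, n = 4)
  out <- balance_images(b$x, b$y, target = 6,
                        policy = augmentation_policy(seed = 1), seed = 2)
  expect_equal(as.integer(table(out$y)), c(6L, 6L))
  expect_equal(sum(out$augmented), 4L)
  expect_false(any(out$augmented[seq_along(b$y)]))
})

test_that("the 30% transfer boundary trains Conv5, Conv6 and the head", {
  m <- freeze_for_transfer(tiny_model(), 0.30)
  expect_setequal(cbmir:::trainable_layer_names(m),
                  c("Conv5-1", "Conv5-2", "Conv5-3", "Conv6", "FC"))
  all_on <- freeze_for_transfer(tiny_model(), 1.0)
  # every parameter-bearing layer: Conv1 + 16 residual units + Conv6 + FC
  expect_length(cbmir:::trainable_layer_names(all_on), 19L)
})

test_that("frozen layers are bit-identical after training", {
  b <- synth_batch(K = 3, n = 4)
  m <- freeze_for_transfer(build_feature_extractor(3, 32, seed = 1), 0.30)
  frozen <- setdiff(
    vapply(m$layers, function(l) l$name %||% "", character(1)),
    c(cbmir:::trainable_layer_names(m), "", "MaxPool", "SoftMax",
      "Classification"))
  before <- model_checksums(m, frozen)
  fr <- fit(m, b$x, b$y, train_config(epochs = 2, seed = 5))
  expect_identical(model_checksums(fr$final_model, frozen), before)
  # trained layers did move
  expect_false(identical(model_checksums(fr$final_model, "FC"),
                         model_checksums(m, "FC")))
})

test_that("zero learning rate leaves every weight unchanged", {
  b <- synth_batch(K = 3, n = 2)
  m <- build_feature_extractor(3, 32, seed = 1)
  fr <- fit(m, b$x, b$y, train_config(epochs = 2, learning_rate = 0,
                                      seed = 5))
  # weights (not batch-norm running statistics, which observe data) frozen
  expect_identical(model_checksums(fr$final_model, stats = FALSE),
                   model_checksums(m, stats = FALSE))
  expect_equal(nrow(fr$history), 2L)
})

test_that("full-batch gradient descent yields a non-increasing loss trend", {
  b <- synth_batch(K = 2, n = 4)
  m <- build_feature_extractor(2, 32, seed = 3)
  # step size inside the stable region of the He-initialized network
  cfg <- train_config(minibatch_size = length(b$y), epochs = 10,
                      learning_rate = 1e-5, momentum = 0,
                      l2_regularization = 0, seed = 1,
                      shuffle_each_epoch = FALSE)
  fr <- fit(m, b$x, b$y, cfg)
  dl <- diff(fr$history$loss)
  expect_lte(sum(dl > 1e-3), 1)
})

test_that("training is reproducible and rejects bad labels", {
  b <- synth_batch(K = 2, n = 3)
  m <- build_feature_extractor(2, 32, seed = 3)
  cfg <- train_config(epochs = 2, seed = 11)
  f1 <- fit(m, b$x, b$y, cfg)
  f2 <- fit(m, b$x, b$y, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(model_checksums(f1$model), model_checksums(f2$model))
  expect_error(fit(m, b$x, b$y + 5L, cfg), "labels")
  expect_error(fit(m, b$x, b$y[-1], cfg), "mismatch")
})

test_that("well-separated classes are fit to high training accuracy", {
  b <- synth_batch(K = 3, n = 30, side = 32, affine_magnitude = 0.1,
                   noise_sd = 0.02)
  m <- build_feature_extractor(3, 32, seed = 6)
  m <- freeze_for_transfer(m, 0.30)
  fr <- fit(m, b$x, b$y, train_config(epochs = 15, seed = 8))
  expect_gte(tail(fr$history$accuracy, 1), 0.95)
  # kept weights are the best epoch's (minimum loss, accuracy tie-break)
  kept <- which.min(fr$history$loss)
  expect_equal(fr$history$loss[kept], min(fr$history$loss))
})
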