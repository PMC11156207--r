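test_that("network shape contracts hold and are fully convolutional", {
  cfg <- unet_config()
  expect_equal(cfg$depth, 7)
  expect_error(unet_config(depth = 5), "length")

  model <- build_unet(seed = 1)
  n_par <- choroidseg:::unet_num_params(model$ptr)
  seg <- predict_scan(model, matrix(runif(128 * 128), 128, 128))
  expect_equal(dim(seg$region_prob), c(128, 128))
  expect_true(all(vapply(seg, function(m) all(m >= 0 & m <= 1), logical(1))))

  # non-square input (peripapillary aspect) through the same weights
  seg2 <- predict_scan(model, matrix(runif(128 * 256), 128, 256))
  expect_equal(dim(seg2$vessel_prob), c(128, 256))
  expect_equal(choroidseg:::unet_num_params(model$ptr), n_par)

  # not divisible by 64: padded then cropped back
  seg3 <- predict_scan(model, matrix(runif(100 * 150), 100, 150))
  expect_equal(dim(seg3$region_prob), c(100, 150))
})

test_that("zero learning rate leaves weights untouched", {
  ds <- generate_dataset(train_fixture_config(1), 2, 1)
  model <- build_unet(seed = 3)
  before <- choroidseg:::unet_get_state(model$ptr)$params
  fit <- train_model(model, ds, train_config(epochs = 3, lr = 0, seed = 1))
  after <- choroidseg:::unet_get_state(model$ptr)$params
  expect_equal(before, after, tolerance = 0)
  expect_equal(fit$history$loss, rep(fit$history$loss[1], 3))
})

test_that("training is seed-deterministic and clips gradient norms", {
  ds <- generate_dataset(train_fixture_config(2), 2, 2)
  m1 <- build_unet(seed = 5)
  h1 <- train_model(m1, ds, train_config(epochs = 4, seed = 9))$history
  m2 <- build_unet(seed = 5)
  h2 <- train_model(m2, ds, train_config(epochs = 4, seed = 9))$history
  expect_identical(h1, h2)
  expect_true(all(h1$grad_norm <= 3 + 1e-6))
})

test_that("a short run overfits one phantom", {
  ds <- generate_dataset(train_fixture_config(4), 1, 4)
  model <- build_unet(seed = 7)
  d0 <- dice_score(predict_scan(model, ds[[1]]$image)$region_prob,
                   ds[[1]]$region_mask)
  fit <- train_model(model, ds, train_config(epochs = 60, seed = 7))
  seg <- predict_scan(model, ds[[1]]$image)
  d1 <- dice_score(seg$region_prob, ds[[1]]$region_mask)
  expect_lt(utils::tail(fit$history$loss, 1), 0.25 * fit$history$loss[1])
  expect_gte(d1, 0.95)
  expect_gt(d1, d0)
})

test_that("checkpoints round-trip through save/load", {
  model <- build_unet(seed = 2)
  x <- matrix(runif(64 * 64), 64, 64)
  ds <- generate_dataset(train_fixture_config(5), 1, 5)
  train_model(model, ds, train_config(epochs = 2, seed = 2))
  p1 <- predict_scan(model, x)
  f <- tempfile(fileext = ".rds")
  save_unet(model, f)
  m2 <- load_unet(f)
  p2 <- predict_scan(m2, x)
  expect_equal(p1, p2, tolerance = 1e-7)
  unlink(f)
})

test_that("augmentations transform image, targets and fovea jointly", {
  s <- generate_dataset(train_fixture_config(6), 1, 6)[[1]]
  tgt <- choroidseg:::sample_targets(s)
  W <- ncol(s$image)

  none <- augmentation_config(hflip_p = 0, photometric_p = 0, affine_p = 0,
                              scale_p = 0)
  aid <- augment_sample(s$image, tgt, s$fovea_col, none, seed = 1)
  expect_identical(aid$image, s$image)
  expect_identical(aid$targets, tgt)
  expect_identical(aid$fovea_col, s$fovea_col)

  flip <- augmentation_config(hflip_p = 1, photometric_p = 0, affine_p = 0,
                              scale_p = 0)
  afl <- augment_sample(s$image, tgt, s$fovea_col, flip, seed = 1)
  expect_identical(afl$fovea_col, W + 1L - s$fovea_col)
  expect_equal(afl$targets[, , 1], tgt[, W:1, 1])

  # rotation: the tracked fovea column follows the warped target's peak
  rot <- augmentation_config(hflip_p = 0, photometric_p = 0, affine_p = 1,
                             scale_p = 0, shear_range = c(0, 0))
  arot <- augment_sample(s$image, tgt, s$fovea_col, rot, seed = 11)
  peak <- which(arot$targets[, , 3] == max(arot$targets[, , 3]),
                arr.ind = TRUE)[1, ]
  expect_lte(abs(arot$fovea_col - peak[2]), 2)

  a1 <- augment_sample(s$image, tgt, s$fovea_col, augmentation_config(),
                       seed = 13)
  a2 <- augment_sample(s$image, tgt, s$fovea_col, augmentation_config(),
                       seed = 13)
  expect_identical(a1, a2)
})
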