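test_that("Dice loss matches its closed form and complements DSC", {
  set.seed(40)
  g <- rand_mask(8)
  expect_equal(dice_loss(g + 0, g), 0)
  expect_equal(dice_loss(1 - g, g), 1)
  expect_equal(dice_loss(matrix(0, 4, 4), matrix(0, 4, 4)), 1)  # 0/0 guard
  # worked 2x2 example: uniform 0.5 prediction against half-ones truth
  pred <- matrix(0.5, 2, 2); gt <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice_loss(pred, gt), 1 / 3)
  for (i in 1:25) {
    p <- rand_mask(10); g <- rand_mask(10)
    dsc <- segmentation_metrics(confusion_counts(p, g))[["DSC"]]
    if (!is.nan(dsc)) expect_equal(dice_loss(p + 0, g) + dsc, 1)
  }
})

test_that("the Dice gradient agrees with numerical differentiation", {
  ns <- asNamespace("speckleseg")
  set.seed(41)
  p <- matrix(runif(16), 4, 4); g <- rand_mask(4)
  an <- ns$dice_loss_grad(p, g)
  for (idx in sample(16, 5)) {
    e <- 1e-6
    pp <- p; pp[idx] <- pp[idx] + e
    pm <- p; pm[idx] <- pm[idx] - e
    expect_equal(an[idx], (dice_loss(pp, g) - dice_loss(pm, g)) / (2 * e),
                 tolerance = 1e-5)
  }
})

test_that("U-Net construction respects its spec", {
  un <- build_unet(unet_spec(depth = 3, base_channels = 4), seed = 2)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  p <- speckleseg:::unet_forward(un$net, x, train = FALSE)
  expect_equal(dim(p), dim(x))
  expect_true(all(is.finite(p) & p >= 0 & p <= 1))
  bigger <- build_unet(unet_spec(depth = 3, base_channels = 8), seed = 2)
  expect_gt(speckleseg:::n_params2(bigger), speckleseg:::n_params2(un))
})

test_that("U-Net training is seeded, reproducible, and learns", {
  set.seed(42)
  imgs <- replicate(8, matrix(runif(16 * 16), 16, 16), simplify = FALSE)
  labs <- lapply(imgs, function(x) (x > 0.6) * 1)  # learnable thresholding task
  sp <- unet_spec(depth = 2, base_channels = 4, dropout_rate = 0.2)
  f1 <- fit_unet(imgs, labs, epochs = 4, lr = 1e-2, batch_size = 4,
                 spec = sp, seed = 5)
  f2 <- fit_unet(imgs, labs, epochs = 4, lr = 1e-2, batch_size = 4,
                 spec = sp, seed = 5)
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history[4], f1$history[1])
  f0 <- fit_unet(imgs, labs, epochs = 0, spec = sp, seed = 5)
  expect_equal(f0$trained_epochs, 0L)
  expect_error(fit_unet(imgs, labs[-1], spec = sp), "paired")
})

test_that("mask prediction thresholds, tiles, and keeps shapes", {
  set.seed(43)
  imgs <- replicate(6, matrix(runif(16 * 16), 16, 16), simplify = FALSE)
  labs <- lapply(imgs, function(x) (x > 0.5) * 1)
  un <- fit_unet(imgs, labs, epochs = 2, lr = 1e-2, batch_size = 4,
                 spec = unet_spec(depth = 2, base_channels = 4), seed = 6)
  img <- matrix(runif(20 * 26), 20, 26)  # forces the padding path
  pr <- predict(un, img, type = "prob", tile = 16)
  mk <- predict(un, img, type = "mask", tile = 16)
  expect_equal(dim(pr), dim(img))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(mk, (pr > 0.5) * 1)
  expect_true(all(mk %in% c(0, 1)))
})

test_that("tiled resampling alone barely degrades a perfect probability map", {
  # feed the ground truth through the inference resampling chain
  # (tile 80 -> 256 -> 80 -> reassemble): the loss measured is the
  # resampling loss only
  set.seed(44)
  gt <- generate_vessel_tree(vessel_tree_params(size = 160, n_roots = 2,
                                                width_range = c(4, 8)),
                             seed = 3)
  tl <- tile_image(gt + 0, tile = 80)
  for (k in seq_along(tl$patches)) {
    up <- resample_patch(tl$patches[[k]]$pixels, 256)
    tl$patches[[k]]$pixels <- resample_patch(up, 80)
  }
  rec <- (reassemble(tl$patches, tl$plan) > 0.5) * 1
  dsc <- segmentation_metrics(confusion_counts(rec, gt))[["DSC"]]
  expect_gte(dsc, 0.98)
})
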