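test_that("the 80/20 split reproduces the study's sizes and is seeded", {
  sp <- split_dataset(140, 0.8, seed = 1)
  expect_length(sp$train, 112)
  expect_length(sp$test, 28)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:140)
  expect_equal(lengths(split_dataset(10, 0.5)[1:2]),
               c(train = 5L, test = 5L))
  expect_identical(split_dataset(140, 0.8, seed = 4),
                   split_dataset(140, 0.8, seed = 4))
  expect_false(identical(split_dataset(140, 0.8, 1), split_dataset(140, 0.8, 2)))
  expect_error(split_dataset(1), "two")
  expect_error(split_dataset(10, 1.2), "strictly")
})

test_that("the learning-rate schedule is flat then linearly decays to zero", {
  expect_equal(lr_schedule(0), 2e-4)
  expect_equal(lr_schedule(99), 2e-4)
  expect_equal(lr_schedule(100), 2e-4)  # knee of the ramp
  expect_equal(lr_schedule(125), 1e-4)
  expect_equal(lr_schedule(150), 0)
  lrs <- lr_schedule(0:150)
  expect_true(all(diff(lrs) <= 0))
  # piecewise-linear integral: base * (2T/3 + T/6)
  expect_equal(sum((lrs[-1] + lrs[-151]) / 2), 2e-4 * (100 + 25))
  expect_error(lr_schedule(-1), "non-negative")
  expect_error(lr_schedule(200), "beyond")
})

test_that("intermediate selection ranks checkpoints by synthesis cosine", {
  set.seed(60)
  pair <- tiny_pair()
  a <- lapply(pair$source$labels[1:4], function(m) m * 0.8 + 0.1)
  b <- pair$target$images[1:4]
  cg <- fit_cyclegan(a, b, epochs = 1, gen = generator_spec(1, 4),
                     disc = discriminator_spec(1, 4),
                     keep_checkpoints = TRUE, seed = 8)
  labs <- pair$source$labels[1:4]
  expect_equal(select_intermediate(cg, a, labs), 1)
  expect_equal(select_intermediate(cg, mode = "last"), 1)
  # degrade a copy of the checkpoint with heavy weight noise: the clean
  # checkpoint must win
  set.seed(61)
  noisy <- lapply(cg$checkpoints[[1]], function(pl)
    lapply(pl, function(w) w + rnorm(length(w), 0, 2)))
  cg$checkpoints[[2]] <- noisy
  cg$epochs <- 2L
  expect_equal(select_intermediate(cg, a, labs), 1)
  # reversed order picks the clean one at position 2
  cg$checkpoints <- cg$checkpoints[c(2, 1)]
  expect_equal(select_intermediate(cg, a, labs), 2)
})

test_that("configs validate, merge, and reject unknown keys", {
  cfg <- validate_config("")
  expect_equal(cfg, default_config())
  cfg2 <- validate_config("synthesis:\n  lambda3: 5\n")
  expect_equal(cfg2$synthesis$lambda3, 5)
  expect_equal(cfg2$synthesis$lambda1, 1)
  expect_error(validate_config("synthesiss:\n  lambda3: 5\n"), "unknown")
  expect_error(validate_config("synthesis:\n  epochs: -3\n"), "epochs")
  expect_error(validate_config("size_match:\n  th: 1.5\n"), "th")
  tiny <- validate_config("", base = tiny_config())
  expect_equal(tiny$patch$size, 64L)
  expect_equal(tiny$size_match$th, 0.13)  # preset keeps the selection rule
})

test_that("the otsu strategy routes around training entirely", {
  pair <- tiny_pair()
  fit <- lsci_adapt(pair$source$images, pair$source$labels,
                    pair$target$images, strategy = "otsu",
                    config = tiny_config(), seed = 1)
  expect_null(fit$cyclegan); expect_null(fit$unet)
  pred <- predict(fit, pair$target$images[[1]])
  expect_equal(dim(pred), dim(pair$target$images[[1]]))
  expect_true(all(pred %in% c(0, 1)))
  expect_error(predict(fit, pair$target$images[[1]], type = "prob"),
               "probabilities")
})

test_that("a joint run with zero segmentation weight reproduces the synthesis-only losses", {
  set.seed(62)
  pair <- tiny_pair()
  cfg <- tiny_config()
  cfg$patch$n_source <- 6L; cfg$patch$n_target <- 6L
  cfg$synthesis$epochs <- 1L; cfg$synthesis$n_res_blocks <- 1L
  cfg$synthesis$base_channels <- 4L; cfg$synthesis$disc_layers <- 1L
  cfg$segmentation$depth <- 2L; cfg$segmentation$base_channels <- 4L
  cfg$segmentation$epochs <- 1L
  cfg$e2e$epochs <- 1L
  cfg$e2e$lambda4 <- 0
  ez <- lsci_adapt(pair$source$images, pair$source$labels,
                   pair$target$images, strategy = "e2e_vdsm",
                   config = cfg, seed = 3)
  ts <- lsci_adapt(pair$source$images, pair$source$labels,
                   pair$target$images, strategy = "2step_vdsm",
                   config = cfg, seed = 3)
  shared <- c("adv_ab", "adv_ba", "cycle", "d_a", "d_b")
  expect_equal(ez$cyclegan$history[1, shared], ts$cyclegan$history[1, shared])
})

test_that("the experiment driver emits one row per strategy per test image", {
  set.seed(63)
  pair <- tiny_pair()
  cfg <- tiny_config()
  data <- list(source = list(images = pair$source$images[1:6],
                             labels = pair$source$labels[1:6]),
               target = list(images = pair$target$images[1:6]),
               test = list(images = pair$target$images[7:9],
                           labels = pair$target_labels[7:9]))
  rep <- run_experiment(data, strategies = "otsu", config = cfg, seed = 2)
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep$per_image), 3)
  expect_equal(unique(rep$per_image$strategy), "otsu")
  expect_true(all(rep$aggregate$n == 3))
  expect_true(all(rep$aggregate$mean >= 0 & rep$aggregate$mean <= 1,
                  na.rm = TRUE))
})
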