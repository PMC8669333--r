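test_that("least-squares adversarial loss hits its optima and worked value", {
  ones <- matrix(1, 4, 4); zeros <- matrix(0, 4, 4); half <- matrix(0.5, 4, 4)
  expect_equal(adversarial_loss(ones, zeros, "discriminator"), 0)
  expect_equal(adversarial_loss(NULL, ones, "generator"), 0)
  expect_equal(adversarial_loss(half, half, "discriminator"), 0.25)
  expect_error(adversarial_loss(ones, matrix(0, 2, 2), "discriminator"),
               "shape")
})

test_that("cycle loss is the mean absolute reconstruction error", {
  x <- matrix(runif(36), 6, 6)
  expect_equal(cycle_loss(x, x), 0)
  expect_equal(cycle_loss(matrix(0, 3, 3), matrix(1, 3, 3)), 1)
  set.seed(50)
  a <- matrix(runif(25), 5); b <- matrix(runif(25), 5)
  brute <- 0
  for (i in 1:25) brute <- brute + abs(a[i] - b[i])
  expect_equal(cycle_loss(a, b), brute / 25)
  expect_error(cycle_loss(a, matrix(0, 2, 2)), "shape")
})

test_that("the combined objective is the weighted sum of its logged terms", {
  set.seed(51)
  cg <- fit_cyclegan(list(matrix(runif(256), 16, 16)),
                     list(matrix(runif(256), 16, 16)),
                     epochs = 0, gen = generator_spec(1, 4),
                     disc = discriminator_spec(1, 4), seed = 3)
  a <- matrix(runif(256), 16, 16); b <- matrix(runif(256), 16, 16)
  l <- synthesis_loss(cg, a, b, weights = c(1, 1, 10))
  expect_equal(l$total,
               l$terms[["adv_ab"]] + l$terms[["adv_ba"]] + 10 * l$terms[["cycle"]])
  proj <- synthesis_loss(cg, a, b, weights = c(0, 0, 1))
  expect_equal(proj$total, proj$terms[["cycle"]])
  expect_true(all(l$terms >= 0))
  expect_error(synthesis_loss(cg, a, b, weights = c(-1, 1, 1)),
               "non-negative")
})

test_that("synthesis training is deterministic under a seed and reduces its objective", {
  set.seed(52)
  a <- replicate(4, matrix(runif(256), 16, 16), simplify = FALSE)
  b <- replicate(4, matrix(runif(256) * 0.5 + 0.4, 16, 16), simplify = FALSE)
  args <- list(a, b, epochs = 2, gen = generator_spec(1, 4),
               disc = discriminator_spec(1, 4), seed = 9)
  f1 <- do.call(fit_cyclegan, args)
  f2 <- do.call(fit_cyclegan, args)
  expect_identical(f1$history, f2$history)
  gc_cyc <- f1$history[, "cycle"]
  expect_lt(gc_cyc[2], gc_cyc[1])
  f0 <- fit_cyclegan(a, b, epochs = 0, gen = generator_spec(1, 4),
                     disc = discriminator_spec(1, 4), seed = 9)
  expect_null(f0$history)
  expect_error(fit_cyclegan(list(), b, epochs = 1), "non-empty")
})

test_that("translation preserves shape and range even untrained", {
  set.seed(53)
  cg <- fit_cyclegan(list(matrix(runif(256), 16, 16)),
                     list(matrix(runif(256), 16, 16)),
                     epochs = 0, gen = generator_spec(1, 4),
                     disc = discriminator_spec(1, 4), seed = 4)
  imgs <- replicate(3, matrix(runif(24 * 24), 24, 24), simplify = FALSE)
  syn <- predict(cg, imgs)
  expect_length(syn, 3)
  for (s in syn) {
    expect_equal(dim(s), c(24, 24))
    expect_true(all(is.finite(s) & s >= 0 & s <= 1))
  }
  one <- predict(cg, imgs[[1]], direction = "ba")
  expect_equal(dim(one), c(24, 24))
})

test_that("synthesis quality scores identity, disjointness, and dilation", {
  set.seed(54)
  m <- generate_vessel_tree(vessel_tree_params(size = 48, width_range = c(2, 3)),
                            seed = 5)
  q <- synthesis_quality(m, m + 0)
  expect_equal(q$cosine, 1)
  expect_equal(q$diameter_ratio, 1)
  a <- matrix(0, 10, 10); a[1:3, ] <- 1
  d <- matrix(0, 10, 10); d[7:9, ] <- 1
  expect_equal(synthesis_quality(a, d)$cosine, 0)
  # a one-pixel bar against its cross-dilation: ratio near 3
  bar <- matrix(0, 64, 64); bar[32, 10:55] <- 1
  q2 <- synthesis_quality(bar, dilate_mask(bar) + 0)
  expect_equal(q2$diameter_ratio, 3, tolerance = 0.05)
  expect_warning(synthesis_quality(matrix(0, 4, 4), matrix(0, 4, 4)),
                 "undefined")
})
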