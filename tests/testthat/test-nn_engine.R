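# The conv-net engine is authored in-package, so its calculus is tested
# against numerical differentiation directly.

num_grad <- function(f, x, idx, e = 1e-6) {
  sapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + e
    xm <- x; xm[i] <- xm[i] - e
    (f(xp) - f(xm)) / (2 * e)
  })
}

test_that("convolution gradients match numerical differentiation", {
  ns <- asNamespace("speckleseg")
  set.seed(70)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  for (pm in c("zero", "reflect")) for (s in c(1L, 2L)) {
    l <- ns$nn_conv(2L, 3L, 3L, stride = s, pad = 1L, pad_mode = pm)
    y <- ns$layer_forward(l, x)
    gy <- array(rnorm(length(y)), dim(y))
    gx <- ns$layer_backward(l, gy)
    f <- function(xa) sum(ns$layer_forward(l, xa) * gy)
    idx <- sample(length(x), 5)
    expect_equal(gx[idx], num_grad(f, x, idx), tolerance = 1e-6)
    widx <- sample(length(l$p$w), 5)
    l$g <- lapply(l$g, function(z) z * 0)
    ns$layer_forward(l, x); ns$layer_backward(l, gy)
    fw <- function(wa) { l$p$w <- wa; sum(ns$layer_forward(l, x) * gy) }
    expect_equal(l$g$w[widx], num_grad(fw, l$p$w, widx), tolerance = 1e-6)
  }
})

test_that("normalization, pooling, and upsampling backprop correctly", {
  ns <- asNamespace("speckleseg")
  set.seed(71)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  for (kind in c("instance", "batch")) {
    l <- ns$nn_norm(3L, kind)
    l$p$gamma <- runif(3, 0.5, 1.5); l$p$beta <- rnorm(3)
    y <- ns$layer_forward(l, x, train = TRUE)
    gy <- array(rnorm(length(y)), dim(y))
    gx <- ns$layer_backward(l, gy)
    f <- function(xa) sum(ns$layer_forward(l, xa, train = TRUE) * gy)
    idx <- sample(length(x), 5)
    expect_equal(gx[idx], num_grad(f, x, idx, e = 1e-5), tolerance = 1e-4)
  }
  for (type in c("maxpool", "upnn")) {
    l <- if (type == "maxpool") ns$nn_maxpool() else ns$nn_upnn()
    y <- ns$layer_forward(l, x)
    gy <- array(rnorm(length(y)), dim(y))
    gx <- ns$layer_backward(l, gy)
    f <- function(xa) sum(ns$layer_forward(l, xa) * gy)
    idx <- sample(length(x), 5)
    expect_equal(gx[idx], num_grad(f, x, idx), tolerance = 1e-5)
  }
})

test_that("whole-network input gradients are exact", {
  ns <- asNamespace("speckleseg")
  set.seed(72)
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  G <- ns$build_generator(generator_spec(1, 4))
  y <- ns$mod_forward(G, x)
  expect_equal(dim(y), dim(x))  # fully convolutional: shape preserved
  gy <- array(rnorm(length(y)), dim(y))
  gx <- ns$mod_backward(G, gy)
  f <- function(xa) sum(ns$mod_forward(G, xa) * gy)
  idx <- sample(length(x), 4)
  expect_equal(gx[idx], num_grad(f, x, idx, e = 1e-5), tolerance = 1e-4)

  un <- build_unet(unet_spec(2, 4, dropout_rate = 0), seed = 1)
  p <- ns$unet_forward(un$net, abs(x) / max(abs(x)), train = TRUE)
  gt <- array((x > 0) * 1, dim(x))
  gp <- ns$dice_loss_grad(p, gt)
  gx <- ns$unet_backward(un$net, gp)
  f2 <- function(xa) dice_loss(ns$unet_forward(un$net, xa, train = TRUE), gt)
  idx <- sample(length(x), 4)
  expect_equal(gx[idx], num_grad(f2, abs(x) / max(abs(x)), idx, e = 1e-5),
               tolerance = 1e-4)
})

test_that("Adam steps follow the bias-corrected update", {
  ns <- asNamespace("speckleseg")
  l <- ns$nn_conv(1L, 1L, 1L)
  l$p$w[] <- 1; l$g$w[] <- 0.5; l$g$b[] <- 0
  st <- new.env(); st$t <- 0L
  ns$adam_step(list(l), lr = 0.1, st, beta1 = 0.9, beta2 = 0.999)
  # first step: mhat = g, vhat = g^2, so the update is ~ -lr * sign(g)
  expect_equal(l$p$w[1], 1 - 0.1 * 0.5 / (0.5 + 1e-8), tolerance = 1e-6)
  expect_equal(st$t, 1L)
})
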