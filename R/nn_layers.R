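# Minimal CPU training engine: layers over (H, W, C, N) arrays.
#
# Each layer is an environment holding parameters `p`, accumulated
# gradients `g`, Adam moments `m`/`v`, and the forward cache. Networks are
# nested tagged lists of layers ("seq", "res") or hand-wired graphs
# (U-Net). Backward passes accumulate into `g`; the optimizer steps and
# zeroes them. All randomness draws from the R RNG so runs are
# reproducible under set.seed().

nn_tensor <- function(x) {
  # promote a matrix / 3-D array to (H, W, C, N)
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

nn_init_w <- function(dims, init) {
  fan_in <- prod(dims[1:3])
  sd <- switch(init,
    gauss = 0.02,                 # DCGAN-style init used by CycleGAN nets
    he    = sqrt(2 / fan_in),
    stop("unknown init"))
  array(stats::rnorm(prod(dims), 0, sd), dims)
}

nn_conv <- function(cin, cout, k, stride = 1L, pad = 0L,
                    pad_mode = c("zero", "reflect"), init = "gauss") {
  pad_mode <- match.arg(pad_mode)
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e$pad_mode <- if (pad_mode == "zero") 0L else 1L
  e$p <- list(w = nn_init_w(c(k, k, cin, cout), init), b = numeric(cout))
  e$g <- lapply(e$p, function(x) x * 0)
  e
}

nn_norm <- function(c, kind = c("instance", "batch")) {
  kind <- match.arg(kind)
  e <- new.env(parent = emptyenv())
  e$type <- kind
  e$p <- list(gamma = rep(1, c), beta = numeric(c))
  e$g <- list(gamma = numeric(c), beta = numeric(c))
  e$run_mean <- numeric(c); e$run_var <- rep(1, c); e$momentum <- 0.9
  e
}

nn_act <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$type <- kind  # relu | lrelu | tanh | sigmoid
  e
}

nn_maxpool <- function() { e <- new.env(parent = emptyenv()); e$type <- "maxpool"; e }
nn_upnn    <- function() { e <- new.env(parent = emptyenv()); e$type <- "upnn"; e }
nn_dropout <- function(rate) {
  e <- new.env(parent = emptyenv()); e$type <- "dropout"; e$rate <- rate; e
}

# ---- forward / backward per layer ------------------------------------------

layer_forward <- function(l, x, train = TRUE) {
  switch(l$type,
    conv = {
      l$x <- x
      conv2d_fw(x, l$p$w, l$p$b, l$stride, l$pad, l$pad_mode)
    },
    instance = {
      d <- dim(x); hw <- d[1] * d[2]
      xm <- matrix(x, hw, d[3] * d[4])
      mu <- colMeans(xm)
      va <- colMeans(xm * xm) - mu * mu
      istd <- 1 / sqrt(va + 1e-5)
      xhat <- (xm - rep(mu, each = hw)) * rep(istd, each = hw)
      gam <- rep(l$p$gamma, times = d[4]); bet <- rep(l$p$beta, times = d[4])
      y <- xhat * rep(gam, each = hw) + rep(bet, each = hw)
      l$xhat <- xhat; l$istd <- istd; l$d <- d
      dim(y) <- d
      y
    },
    batch = {
      d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
      xp <- aperm(x, c(1, 2, 4, 3)); dim(xp) <- c(hw * N, C)
      if (train) {
        mu <- colMeans(xp)
        va <- colMeans(xp * xp) - mu * mu
        l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * mu
        l$run_var  <- l$momentum * l$run_var  + (1 - l$momentum) * va
      } else {
        mu <- l$run_mean; va <- l$run_var
      }
      istd <- 1 / sqrt(va + 1e-5)
      xhat <- (xp - rep(mu, each = hw * N)) * rep(istd, each = hw * N)
      y <- xhat * rep(l$p$gamma, each = hw * N) + rep(l$p$beta, each = hw * N)
      l$xhat <- if (train) xhat else NULL; l$istd <- istd; l$d <- d
      dim(y) <- c(d[1], d[2], N, C)
      aperm(y, c(1, 2, 4, 3))
    },
    relu = { l$mask <- x > 0; x * l$mask },
    lrelu = { l$mask <- x > 0; ifelse(l$mask, x, 0.2 * x) },
    tanh = { y <- tanh(x); l$y <- y; y },
    sigmoid = { y <- 1 / (1 + exp(-x)); l$y <- y; y },
    maxpool = {
      d <- dim(x)
      i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
      j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
      a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
      cc <- x[i1, j2, , , drop = FALSE]; dd <- x[i2, j2, , , drop = FALSE]
      y <- pmax(a, b, cc, dd)
      l$which <- (a == y) + 2L * (b == y & a != y) +
        3L * (cc == y & a != y & b != y) +
        4L * (dd == y & a != y & b != y & cc != y)
      l$d <- d
      y
    },
    upnn = {
      d <- dim(x); l$d <- d
      x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
        drop = FALSE]
    },
    dropout = {
      if (train && l$rate > 0) {
        l$mask <- (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
        dim(l$mask) <- dim(x)
        x * l$mask
      } else { l$mask <- NULL; x }
    },
    stop("unknown layer type ", l$type))
}

layer_backward <- function(l, gy) {
  switch(l$type,
    conv = {
      r <- conv2d_bw(l$x, l$p$w, gy, l$stride, l$pad, l$pad_mode)
      l$g$w <- l$g$w + r$gw; l$g$b <- l$g$b + r$gb
      l$x <- NULL
      r$gx
    },
    instance = {
      d <- l$d; hw <- d[1] * d[2]
      gym <- matrix(gy, hw, d[3] * d[4])
      gam <- rep(rep(l$p$gamma, times = d[4]), each = hw)
      gxh <- gym * gam
      sg  <- colMeans(gxh)
      sgx <- colMeans(gxh * l$xhat)
      gx <- (gxh - rep(sg, each = hw) - l$xhat * rep(sgx, each = hw)) *
        rep(l$istd, each = hw)
      ggam <- rowSums(matrix(colSums(gym * l$xhat), d[3], d[4]))
      gbet <- rowSums(matrix(colSums(gym), d[3], d[4]))
      l$g$gamma <- l$g$gamma + ggam; l$g$beta <- l$g$beta + gbet
      l$xhat <- NULL
      dim(gx) <- d
      gx
    },
    batch = {
      d <- l$d; hw <- d[1] * d[2]; C <- d[3]; N <- d[4]; m <- hw * N
      gp <- aperm(gy, c(1, 2, 4, 3)); dim(gp) <- c(m, C)
      gxh <- gp * rep(l$p$gamma, each = m)
      sg  <- colMeans(gxh)
      sgx <- colMeans(gxh * l$xhat)
      gx <- (gxh - rep(sg, each = m) - l$xhat * rep(sgx, each = m)) *
        rep(l$istd, each = m)
      l$g$gamma <- l$g$gamma + colSums(gp * l$xhat)
      l$g$beta  <- l$g$beta + colSums(gp)
      l$xhat <- NULL
      dim(gx) <- c(d[1], d[2], N, C)
      aperm(gx, c(1, 2, 4, 3))
    },
    relu = gy * l$mask,
    lrelu = ifelse(l$mask, gy, 0.2 * gy),
    tanh = gy * (1 - l$y^2),
    sigmoid = gy * l$y * (1 - l$y),
    maxpool = {
      d <- l$d
      gx <- array(0, d)
      i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
      for (q in 1:4) {
        sel <- l$which == q
        sub <- array(0, dim(sel))
        sub[sel] <- gy[sel]
        di <- (q - 1L) %% 2L; dj <- (q - 1L) %/% 2L
        gx[i1 + di, j1 + dj, , ] <- sub
      }
      gx
    },
    upnn = {
      d <- l$d
      i1 <- seq(1L, 2L * d[1], 2L); j1 <- seq(1L, 2L * d[2], 2L)
      gy[i1, j1, , , drop = FALSE] + gy[i1 + 1L, j1, , , drop = FALSE] +
        gy[i1, j1 + 1L, , , drop = FALSE] + gy[i1 + 1L, j1 + 1L, , , drop = FALSE]
    },
    dropout = if (is.null(l$mask)) gy else gy * l$mask,
    stop("unknown layer type ", l$type))
}

# ---- composite modules ------------------------------------------------------

nn_seq <- function(...) list(kind = "seq", items = list(...))
nn_res <- function(inner) list(kind = "res", inner = inner)

mod_forward <- function(m, x, train = TRUE) {
  if (is.environment(m)) return(layer_forward(m, x, train))
  switch(m$kind,
    seq = { for (it in m$items) x <- mod_forward(it, x, train); x },
    res = x + mod_forward(m$inner, x, train),
    stop("unknown module"))
}

mod_backward <- function(m, gy) {
  if (is.environment(m)) return(layer_backward(m, gy))
  switch(m$kind,
    seq = { for (it in rev(m$items)) gy <- mod_backward(it, gy); gy },
    res = gy + mod_backward(m$inner, gy),
    stop("unknown module"))
}

collect_layers <- function(m) {
  if (is.environment(m)) return(if (!is.null(m$p)) list(m) else list())
  if (is.list(m) && !is.null(m$kind)) {
    inner <- if (m$kind == "seq") m$items else list(m$inner)
    return(do.call(c, lapply(inner, collect_layers)))
  }
  if (is.list(m)) return(do.call(c, lapply(m, collect_layers)))
  list()
}

n_params <- function(m) sum(vapply(collect_layers(m),
  function(l) sum(vapply(l$p, length, 1L)), 1))

zero_grads <- function(layers) {
  for (l in layers) l$g <- lapply(l$g, function(x) x * 0)
  invisible(NULL)
}

# One Adam update over all parameters of `layers`; `state` is an
# environment holding the shared step counter.
adam_step <- function(layers, lr, state, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in layers) {
    if (is.null(l$m)) { l$m <- lapply(l$g, function(x) x * 0); l$v <- l$m }
    for (nm in names(l$p)) {
      l$m[[nm]] <- beta1 * l$m[[nm]] + (1 - beta1) * l$g[[nm]]
      l$v[[nm]] <- beta2 * l$v[[nm]] + (1 - beta2) * l$g[[nm]]^2
      l$p[[nm]] <- l$p[[nm]] -
        lr * (l$m[[nm]] / c1) / (sqrt(l$v[[nm]] / c2) + eps)
    }
  }
  invisible(NULL)
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}
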