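# Network builders: ResNet generator and PatchGAN discriminator for the
# synthesis stage, U-Net for segmentation. All fully convolutional,
# single-channel in and out.

#' Generator architecture description
#'
#' The translation generators follow the reference cycle-consistent
#' recipe: a 7x7 stem, two stride-2 downsamplings, `n_res_blocks`
#' residual blocks, two nearest-neighbour upsamplings with 3x3
#' convolutions, and a 7x7 head with tanh output; instance
#' normalization and reflection padding throughout.
#'
#' @param n_res_blocks number of residual blocks at the bottleneck.
#' @param base_channels channels after the stem; doubled at each
#'   downsampling.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(n_res_blocks = 9L, base_channels = 64L) {
  stopifnot(n_res_blocks >= 1L, base_channels >= 1L)
  structure(list(n_res_blocks = as.integer(n_res_blocks),
                 base_channels = as.integer(base_channels),
                 n_downsamplings = 2L),
            class = "generator_spec")
}

#' Discriminator architecture description
#'
#' Patch-level discriminator: a stack of stride-2 4x4 convolutions with
#' leaky ReLU, emitting a spatial grid of realness scores rather than a
#' scalar.
#'
#' @param n_layers number of stride-2 convolution layers.
#' @param base_channels channels of the first layer.
#' @return a `discriminator_spec` list.
#' @export
discriminator_spec <- function(n_layers = 3L, base_channels = 64L) {
  stopifnot(n_layers >= 1L, base_channels >= 1L)
  structure(list(n_layers = as.integer(n_layers),
                 base_channels = as.integer(base_channels)),
            class = "discriminator_spec")
}

build_generator <- function(spec) {
  f <- spec$base_channels
  conv_in <- function(cin, cout, k, s, p, pm = "zero")
    nn_seq(nn_conv(cin, cout, k, s, p, pm), nn_norm(cout, "instance"),
           nn_act("relu"))
  items <- list(conv_in(1L, f, 7L, 1L, 3L, "reflect"))
  ch <- f
  for (i in seq_len(spec$n_downsamplings)) {
    items <- c(items, list(conv_in(ch, 2L * ch, 3L, 2L, 1L)))
    ch <- 2L * ch
  }
  for (i in seq_len(spec$n_res_blocks)) {
    inner <- nn_seq(nn_conv(ch, ch, 3L, 1L, 1L, "reflect"),
                    nn_norm(ch, "instance"), nn_act("relu"),
                    nn_conv(ch, ch, 3L, 1L, 1L, "reflect"),
                    nn_norm(ch, "instance"))
    items <- c(items, list(nn_res(inner)))
  }
  for (i in seq_len(spec$n_downsamplings)) {
    items <- c(items, list(nn_seq(nn_upnn()), conv_in(ch, ch %/% 2L, 3L, 1L, 1L)))
    ch <- ch %/% 2L
  }
  items <- c(items, list(nn_seq(nn_conv(ch, 1L, 7L, 1L, 3L, "reflect"),
                                nn_act("tanh"))))
  net <- list(kind = "seq", items = items)
  net
}

build_discriminator <- function(spec) {
  f <- spec$base_channels
  items <- list(nn_seq(nn_conv(1L, f, 4L, 2L, 1L), nn_act("lrelu")))
  ch <- f
  for (i in seq_len(spec$n_layers - 1L)) {
    items <- c(items, list(nn_seq(nn_conv(ch, 2L * ch, 4L, 2L, 1L),
                                  nn_norm(2L * ch, "instance"),
                                  nn_act("lrelu"))))
    ch <- 2L * ch
  }
  items <- c(items, list(nn_seq(nn_conv(ch, 2L * ch, 4L, 1L, 1L),
                                nn_norm(2L * ch, "instance"),
                                nn_act("lrelu"),
                                nn_conv(2L * ch, 1L, 4L, 1L, 1L))))
  list(kind = "seq", items = items)
}

#' U-Net architecture description
#'
#' @param depth number of resolution levels (encoder stages including
#'   the bottleneck); input sides must be divisible by `2^(depth-1)`.
#' @param base_channels channels at the top level; doubled per level.
#' @param dropout_rate dropout probability applied at the two deepest
#'   levels during training.
#' @param use_batchnorm use batch normalization after each convolution.
#' @return a `unet_spec` list.
#' @export
unet_spec <- function(depth = 4L, base_channels = 64L, dropout_rate = 0.4,
                      use_batchnorm = TRUE) {
  stopifnot(depth >= 1L, dropout_rate >= 0, dropout_rate < 1)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 dropout_rate = dropout_rate,
                 use_batchnorm = use_batchnorm),
            class = "unet_spec")
}

unet_conv_block <- function(cin, cout, spec, dropout = FALSE) {
  norm <- function(c) if (spec$use_batchnorm) list(nn_norm(c, "batch")) else list()
  items <- c(list(nn_conv(cin, cout, 3L, 1L, 1L, init = "he")), norm(cout),
             list(nn_act("relu")),
             list(nn_conv(cout, cout, 3L, 1L, 1L, init = "he")), norm(cout),
             list(nn_act("relu")))
  if (dropout && spec$dropout_rate > 0)
    items <- c(items, list(nn_dropout(spec$dropout_rate)))
  list(kind = "seq", items = items)
}

# Hand-wired encoder/decoder graph with channel-concatenating skips.
build_unet_net <- function(spec) {
  d <- spec$depth; f <- spec$base_channels
  enc <- vector("list", d); pools <- vector("list", max(d - 1L, 0L))
  ch_in <- 1L
  for (i in seq_len(d)) {
    ch_out <- f * 2L^(i - 1L)
    enc[[i]] <- unet_conv_block(ch_in, ch_out, spec, dropout = i >= d - 1L)
    if (i < d) pools[[i]] <- nn_maxpool()
    ch_in <- ch_out
  }
  ups <- vector("list", max(d - 1L, 0L)); upconv <- ups; dec <- ups
  for (i in rev(seq_len(d - 1L))) {
    ch_hi <- f * 2L^i; ch_lo <- f * 2L^(i - 1L)
    ups[[i]] <- nn_upnn()
    upconv[[i]] <- nn_conv(ch_hi, ch_lo, 3L, 1L, 1L, init = "he")
    dec[[i]] <- unet_conv_block(2L * ch_lo, ch_lo, spec, dropout = FALSE)
  }
  final <- nn_conv(f, 1L, 1L, 1L, 0L, init = "he")
  sig <- nn_act("sigmoid")
  list(enc = enc, pools = pools, ups = ups, upconv = upconv, dec = dec,
       final = final, sig = sig, depth = d)
}

unet_forward <- function(net, x, train = TRUE) {
  d <- net$depth
  skips <- vector("list", d)
  h <- x
  for (i in seq_len(d)) {
    h <- mod_forward(net$enc[[i]], h, train)
    skips[[i]] <- h
    if (i < d) h <- layer_forward(net$pools[[i]], h, train)
  }
  for (i in rev(seq_len(d - 1L))) {
    h <- layer_forward(net$ups[[i]], h, train)
    h <- layer_forward(net$upconv[[i]], h, train)
    h <- cat_channels(skips[[i]], h)
    h <- mod_forward(net$dec[[i]], h, train)
  }
  h <- layer_forward(net$final, h, train)
  layer_forward(net$sig, h, train)
}

unet_backward <- function(net, gy) {
  d <- net$depth
  g <- layer_backward(net$sig, gy)
  g <- layer_backward(net$final, g)
  gskips <- vector("list", d)
  for (i in seq_len(d - 1L)) {
    g <- mod_backward(net$dec[[i]], g)
    nlo <- dim(g)[3] %/% 2L
    gskips[[i]] <- g[, , seq_len(nlo), , drop = FALSE]
    g <- g[, , nlo + seq_len(nlo), , drop = FALSE]
    g <- layer_backward(net$upconv[[i]], g)
    g <- layer_backward(net$ups[[i]], g)
  }
  # g now reaches the bottleneck encoder output
  for (i in rev(seq_len(d))) {
    if (i < d) {
      g <- layer_backward(net$pools[[i]], g)
      g <- g + gskips[[i]]
    }
    g <- mod_backward(net$enc[[i]], g)
  }
  g
}

unet_layers <- function(net)
  c(collect_layers(net$enc), collect_layers(net$pools),
    collect_layers(net$ups), collect_layers(net$upconv),
    collect_layers(net$dec), collect_layers(net$final))
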