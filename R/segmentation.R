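# U-Net vessel segmenter trained on synthetic speckle-style patches with
# their fundus-derived labels, under the Dice overlap loss.

#' Dice loss
#'
#' `1 - 2 * sum(p * g) / (sum(p^2) + sum(g^2))` over all pixels, the
#' soft overlap loss minimized during segmentation training. For a
#' binary prediction it equals `1 - DSC`. No additive smoothing is used;
#' an epsilon only guards the degenerate 0/0 case (both inputs empty),
#' which returns 1.
#'
#' @param pred predicted probability map (values in `[0,1]`).
#' @param gt binary ground-truth mask, same shape.
#' @param eps guard for an all-zero denominator (default 1e-7).
#' @return a scalar in `[0,1]` for inputs in `[0,1]`.
#' @export
dice_loss <- function(pred, gt, eps = 1e-7) {
  if (length(pred) != length(gt)) stop("shape mismatch in dice_loss")
  den <- sum(pred^2) + sum(gt^2)
  if (den < eps) return(1)
  1 - 2 * sum(pred * gt) / den
}

# analytic gradient of dice_loss with respect to pred
dice_loss_grad <- function(pred, gt, eps = 1e-7) {
  den <- sum(pred^2) + sum(gt^2)
  if (den < eps) return(pred * 0)
  s <- sum(pred * gt)
  (4 * pred * s - 2 * gt * den) / den^2
}

#' Construct an untrained U-Net
#'
#' Builds the encoder-decoder network with skip connections described by
#' a [unet_spec()]: per level two 3x3 convolutions (batch-normalized,
#' ReLU), 2x2 max pooling on the way down, nearest-neighbour upsampling
#' plus convolution on the way up, channel-concatenating skips, a 1x1
#' convolution and sigmoid head. Dropout acts at the two deepest levels.
#'
#' @param spec a [unet_spec()].
#' @param seed RNG seed for weight initialization.
#' @return an object of class `unet` (untrained).
#' @export
build_unet <- function(spec = unet_spec(), seed = 1L) {
  set.seed(seed)
  structure(list(net = build_unet_net(spec), spec = spec, history = NULL,
                 input_size = NA_integer_, trained_epochs = 0L, seed = seed),
            class = "unet")
}

stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d[1], d[2], 1L, length(lst)))
  for (i in seq_along(lst)) out[, , 1L, i] <- lst[[i]]
  out
}

#' Fit the U-Net segmenter
#'
#' Trains a U-Net on image patches paired with binary label masks by
#' minimizing the mean per-patch Dice loss with Adam (defaults: 100
#' epochs, learning rate 1e-4, batch size 8, dropout 0.4, batch
#' normalization).
#'
#' @param patches list of grayscale matrices in `[0,1]`, all the same
#'   square size (side divisible by `2^(depth-1)`).
#' @param labels list of binary masks congruent with `patches`.
#' @param epochs,lr,batch_size optimization settings.
#' @param spec a [unet_spec()].
#' @param seed RNG seed (initialization, shuffling, dropout).
#' @param verbose print per-epoch loss.
#' @return an object of class `unet` with the trained network and the
#'   per-epoch mean Dice-loss `history`.
#' @seealso [predict.unet()], [dice_loss()]
#' @export
fit_unet <- function(patches, labels, epochs = 100L, lr = 1e-4,
                     batch_size = 8L, spec = unet_spec(), seed = 1L,
                     verbose = FALSE) {
  if (length(patches) != length(labels) || length(patches) == 0L)
    stop("patches and labels must be non-empty and paired")
  for (i in seq_along(patches))
    if (!identical(dim(patches[[i]]), dim(labels[[i]])))
      stop("patch/label shape mismatch at index ", i)
  n <- length(patches)
  model <- build_unet(spec, seed = seed)
  net <- model$net
  layers <- unet_layers(net)
  opt <- new.env(); opt$t <- 0L
  hist <- numeric(0)
  if (epochs > 0L) {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        x <- stack_batch(patches[idx])
        g <- stack_batch(labels[idx])
        p <- unet_forward(net, x, train = TRUE)
        bl <- 0
        gp <- p * 0
        for (k in seq_along(idx)) {
          pk <- p[, , , k, drop = FALSE]; gk <- g[, , , k, drop = FALSE]
          bl <- bl + dice_loss(pk, gk)
          gp[, , , k] <- dice_loss_grad(pk, gk) / length(idx)
        }
        bl <- bl / length(idx)
        unet_backward(net, gp)
        adam_step(layers, lr, opt, beta1 = 0.9)
        zero_grads(layers)
        ep_loss <- ep_loss + bl; nb <- nb + 1L
      }
      hist[ep] <- ep_loss / nb
      if (verbose) message(sprintf("epoch %d/%d  dice loss %.4f", ep, epochs, hist[ep]))
    }
  }
  model$history <- hist
  model$input_size <- nrow(patches[[1]])
  model$trained_epochs <- as.integer(epochs)
  model
}

#' Segment an image with a fitted U-Net
#'
#' Full-image inference follows the tiling scheme: the image is cut into
#' non-overlapping tiles (reflection-padded to a whole grid), each tile
#' is upsampled bilinearly to the network's training size, passed
#' through the network, the probability map is downsampled back to tile
#' size, tiles are reassembled, and (for masks) thresholded.
#'
#' @param object a fitted `unet`.
#' @param newdata a grayscale matrix in `[0,1]`, or a list of them.
#' @param type `"mask"` (default) for a binary mask thresholded at
#'   `threshold`, or `"prob"` for the probability map.
#' @param threshold probability cut for `type = "mask"` (default 0.5).
#' @param tile tile side used at inference (default 80).
#' @param ... unused.
#' @return matrix (or list of matrices) of the input shape.
#' @export
predict.unet <- function(object, newdata, type = c("mask", "prob"),
                         threshold = 0.5, tile = 80L, ...) {
  type <- match.arg(type)
  single <- is.matrix(newdata)
  if (single) newdata <- list(newdata)
  if (is.na(object$input_size))
    stop("network has no input size; fit it or set input_size")
  out <- lapply(newdata, function(img) {
    tl <- tile_image(img, tile = tile)
    up <- lapply(tl$patches, function(p)
      resample_patch(p$pixels, object$input_size, kind = "image_bilinear"))
    x <- stack_batch(up)
    pr <- unet_forward(object$net, x, train = FALSE)
    probs <- lapply(seq_along(up), function(k) {
      m <- matrix(pr[, , 1L, k], object$input_size, object$input_size)
      resample_patch(m, tile, kind = "image_bilinear")
    })
    for (k in seq_along(tl$patches)) tl$patches[[k]]$pixels <- probs[[k]]
    pm <- reassemble(tl$patches, tl$plan)
    if (type == "prob") pm else (pm > threshold) * 1
  })
  if (single) out[[1]] else out
}

#' @export
print.unet <- function(x, ...) {
  s <- x$spec
  cat("U-Net segmenter\n")
  cat(sprintf("  depth %d, base %d channels, dropout %.2f, batchnorm %s (%s params)\n",
              s$depth, s$base_channels, s$dropout_rate,
              if (s$use_batchnorm) "on" else "off",
              format(n_params2(x), big.mark = ",")))
  if (x$trained_epochs > 0L)
    cat(sprintf("  trained %d epochs at %dx%d; final Dice loss %.4f\n",
                x$trained_epochs, x$input_size, x$input_size,
                x$history[length(x$history)]))
  else cat("  untrained\n")
  invisible(x)
}

n_params2 <- function(x) sum(vapply(unet_layers(x$net),
  function(l) sum(vapply(l$p, length, 1L)), 1))

#' @export
plot.unet <- function(x, ...) {
  if (is.null(x$history) || !length(x$history)) stop("no training history")
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "mean Dice loss", ...)
  invisible(x)
}

#' @export
summary.unet <- function(object, ...) {
  print(object)
  if (length(object$history))
    cat(sprintf("  Dice loss: initial %.4f, min %.4f\n",
                object$history[1], min(object$history)))
  invisible(object)
}
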