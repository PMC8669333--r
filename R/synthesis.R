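# Cycle-consistent adversarial translation from the fundus-style source
# domain (A) to the speckle-style target domain (B), and the synthesis
# quality measures (cosine similarity, vessel-diameter ratio).

to_pm1 <- function(x) 2 * x - 1
from_pm1 <- function(x) (x + 1) / 2

#' Least-squares adversarial loss
#'
#' Least-squares GAN formulation. On the discriminator side the loss is
#' `mean((D(real) - 1)^2 + D(fake)^2) / 2`; on the generator side it is
#' `mean((D(fake) - 1)^2)`, pushing synthetic images towards the
#' discriminator's "real" label.
#'
#' @param disc_scores_real discriminator score grid on real images
#'   (ignored on the generator side; may be `NULL`).
#' @param disc_scores_fake discriminator score grid on synthetic images.
#' @param side `"generator"` or `"discriminator"`.
#' @return a non-negative scalar.
#' @export
adversarial_loss <- function(disc_scores_real, disc_scores_fake,
                             side = c("generator", "discriminator")) {
  side <- match.arg(side)
  if (side == "generator")
    return(mean((disc_scores_fake - 1)^2))
  if (!identical(dim(disc_scores_real), dim(disc_scores_fake)) &&
      length(disc_scores_real) != length(disc_scores_fake))
    stop("real and fake score grids must have the same shape")
  (mean((disc_scores_real - 1)^2) + mean(disc_scores_fake^2)) / 2
}

#' Cycle-consistency loss
#'
#' Mean absolute difference between an image and its round-trip
#' translation (A to B and back).
#'
#' @param x original image array.
#' @param x_reconstructed round-trip reconstruction, same shape.
#' @return mean absolute error, a non-negative scalar.
#' @export
cycle_loss <- function(x, x_reconstructed) {
  if (length(x) != length(x_reconstructed) ||
      !identical(dim(x), dim(x_reconstructed)))
    stop("shape mismatch in cycle_loss")
  mean(abs(x - x_reconstructed))
}

#' Combined synthesis objective on one image pair
#'
#' Evaluates the full synthesis loss
#' `lambda1 * L_GAN(G_AB, D_B) + lambda2 * L_GAN(G_BA, D_A) + lambda3 * L_cyc`
#' on one unpaired (A, B) image pair under the current networks, without
#' updating them. Used for logging and additivity checks.
#'
#' @param state a `cyclegan` model (or its internal network state).
#' @param a,b images in `[0,1]` from domains A and B.
#' @param weights numeric `c(lambda1, lambda2, lambda3)`, all `>= 0`.
#' @return list with `total` and per-term `terms`.
#' @export
synthesis_loss <- function(state, a, b, weights = c(1, 1, 10)) {
  if (any(weights < 0)) stop("loss weights must be non-negative")
  st <- if (inherits(state, "cyclegan")) state$state else state
  ta <- nn_tensor(to_pm1(a)); tb <- nn_tensor(to_pm1(b))
  fake_b <- mod_forward(st$G_ab, ta, train = FALSE)
  rec_a  <- mod_forward(st$G_ba, fake_b, train = FALSE)
  fake_a <- mod_forward(st$G_ba, tb, train = FALSE)
  rec_b  <- mod_forward(st$G_ab, fake_a, train = FALSE)
  terms <- c(
    adv_ab = adversarial_loss(NULL, mod_forward(st$D_b, fake_b, FALSE), "generator"),
    adv_ba = adversarial_loss(NULL, mod_forward(st$D_a, fake_a, FALSE), "generator"),
    cycle  = cycle_loss(ta, rec_a) + cycle_loss(tb, rec_b))
  list(total = sum(weights * terms), terms = terms, weights = weights)
}

init_cyclegan <- function(gen, disc) {
  st <- list(G_ab = build_generator(gen), G_ba = build_generator(gen),
             D_a = build_discriminator(disc), D_b = build_discriminator(disc))
  st$gen_layers <- c(collect_layers(st$G_ab), collect_layers(st$G_ba))
  st$da_layers <- collect_layers(st$D_a)
  st$db_layers <- collect_layers(st$D_b)
  st$opt_g <- new.env(); st$opt_g$t <- 0L
  st$opt_da <- new.env(); st$opt_da$t <- 0L
  st$opt_db <- new.env(); st$opt_db$t <- 0L
  st
}

new_image_buffer <- function(capacity = 50L) {
  e <- new.env(parent = emptyenv())
  e$capacity <- capacity; e$images <- list()
  e
}

# Reference replay buffer: returns the incoming image while the buffer
# fills; afterwards returns either the incoming image or swaps it with a
# stored one, with equal probability.
buffer_query <- function(buf, img) {
  if (buf$capacity <= 0L) return(img)
  if (length(buf$images) < buf$capacity) {
    buf$images[[length(buf$images) + 1L]] <- img
    return(img)
  }
  if (stats::runif(1) < 0.5) return(img)
  i <- sample.int(length(buf$images), 1L)
  old <- buf$images[[i]]
  buf$images[[i]] <- img
  old
}

get_params <- function(net) lapply(collect_layers(net), function(l) l$p)
set_params <- function(net, params) {
  ls <- collect_layers(net)
  for (i in seq_along(ls)) ls[[i]]$p <- params[[i]]
  invisible(NULL)
}

# Shared optimization loop for the synthesis-only objective and the
# joint objective with a segmentation term (lambda4 > 0, unet supplied).
cyclegan_train_loop <- function(st, a_imgs, b_imgs, epochs, base_lr,
                                lambda1, lambda2, lambda3,
                                lambda4 = 0, unet = NULL, a_labels = NULL,
                                buffer_size = 50L, beta1 = 0.5,
                                keep_checkpoints = FALSE, verbose = FALSE) {
  na <- length(a_imgs); nb <- length(b_imgs)
  if (na == 0L || nb == 0L) stop("both domains must be non-empty")
  buf_a <- new_image_buffer(buffer_size); buf_b <- new_image_buffer(buffer_size)
  e2e <- lambda4 > 0 && !is.null(unet)
  ulayers <- if (e2e) unet_layers(unet$net) else list()
  opt_u <- new.env(); opt_u$t <- 0L
  hist <- list(); checkpoints <- list()
  term_names <- c("adv_ab", "adv_ba", "cycle", "dice", "d_a", "d_b", "total")

  for (ep in seq_len(epochs)) {
    lr <- lr_schedule(ep - 1L, total_epochs = epochs, base_lr = base_lr)
    n_iter <- max(na, nb)
    ord_a <- sample(rep_len(sample.int(na), n_iter))
    ord_b <- sample(rep_len(sample.int(nb), n_iter))
    acc <- numeric(length(term_names)); names(acc) <- term_names
    for (it in seq_len(n_iter)) {
      ia <- ord_a[it]; ib <- ord_b[it]
      a <- nn_tensor(to_pm1(a_imgs[[ia]]))
      b <- nn_tensor(to_pm1(b_imgs[[ib]]))

      ## ---- generator (and, jointly, segmenter) update -------------------
      # path A: a -> fake_b -> rec_a (+ segmentation on fake_b)
      fake_b <- mod_forward(st$G_ab, a)
      d_fb <- mod_forward(st$D_b, fake_b)
      rec_a <- mod_forward(st$G_ba, fake_b)
      l_adv_ab <- adversarial_loss(NULL, d_fb, "generator")
      l_cyc_a <- cycle_loss(a, rec_a)
      g_fb <- mod_backward(st$D_b, lambda1 * 2 * (d_fb - 1) / length(d_fb))
      g_fb <- g_fb + mod_backward(st$G_ba,
        lambda3 * sign(rec_a - a) / length(rec_a))
      l_dice <- 0
      if (e2e) {
        p <- unet_forward(unet$net, from_pm1(fake_b), train = TRUE)
        gt <- nn_tensor(a_labels[[ia]])
        l_dice <- dice_loss(p, gt)
        gp <- lambda4 * dice_loss_grad(p, gt)
        g_fb <- g_fb + 0.5 * unet_backward(unet$net, gp)
      }
      mod_backward(st$G_ab, g_fb)

      # path B: b -> fake_a -> rec_b
      fake_a <- mod_forward(st$G_ba, b)
      d_fa <- mod_forward(st$D_a, fake_a)
      rec_b <- mod_forward(st$G_ab, fake_a)
      l_adv_ba <- adversarial_loss(NULL, d_fa, "generator")
      l_cyc_b <- cycle_loss(b, rec_b)
      g_fa <- mod_backward(st$D_a, lambda2 * 2 * (d_fa - 1) / length(d_fa))
      g_fa <- g_fa + mod_backward(st$G_ab,
        lambda3 * sign(rec_b - b) / length(rec_b))
      mod_backward(st$G_ba, g_fa)

      adam_step(st$gen_layers, lr, st$opt_g, beta1 = beta1)
      zero_grads(st$gen_layers)
      if (e2e) {
        adam_step(ulayers, lr, opt_u, beta1 = beta1)
        zero_grads(ulayers)
      }
      zero_grads(st$da_layers); zero_grads(st$db_layers)

      ## ---- discriminator updates ---------------------------------------
      fb_q <- buffer_query(buf_b, fake_b)
      d_r <- mod_forward(st$D_b, b)
      mod_backward(st$D_b, (d_r - 1) / length(d_r))
      d_f <- mod_forward(st$D_b, fb_q)
      mod_backward(st$D_b, d_f / length(d_f))
      l_db <- (mean((d_r - 1)^2) + mean(d_f^2)) / 2
      adam_step(st$db_layers, lr, st$opt_db, beta1 = beta1)
      zero_grads(st$db_layers)

      fa_q <- buffer_query(buf_a, fake_a)
      d_r <- mod_forward(st$D_a, a)
      mod_backward(st$D_a, (d_r - 1) / length(d_r))
      d_f <- mod_forward(st$D_a, fa_q)
      mod_backward(st$D_a, d_f / length(d_f))
      l_da <- (mean((d_r - 1)^2) + mean(d_f^2)) / 2
      adam_step(st$da_layers, lr, st$opt_da, beta1 = beta1)
      zero_grads(st$da_layers)

      cyc <- l_cyc_a + l_cyc_b
      tot <- lambda1 * l_adv_ab + lambda2 * l_adv_ba + lambda3 * cyc +
        lambda4 * l_dice
      acc <- acc + c(l_adv_ab, l_adv_ba, cyc, l_dice, l_da, l_db, tot)
    }
    acc <- acc / n_iter
    hist[[ep]] <- c(epoch = ep, lr = lr, acc)
    if (keep_checkpoints) checkpoints[[ep]] <- get_params(st$G_ab)
    if (verbose)
      message(sprintf("epoch %d/%d  total %.4f  cycle %.4f", ep, epochs,
                      acc[["total"]], acc[["cycle"]]))
  }
  list(history = do.call(rbind, hist), checkpoints = checkpoints)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the cycle-consistent synthesis model
#'
#' Trains two generators and two patch discriminators on unpaired images
#' from the source (A, fundus-style) and target (B, speckle-style)
#' domains, minimizing the weighted sum of two least-squares adversarial
#' losses and the cycle-consistency loss. Adam with batch size 1; the
#' learning rate is constant for the first two thirds of the epochs and
#' then decays linearly to zero; discriminators are updated against a
#' replay buffer of past synthetic images.
#'
#' @param domain_a,domain_b lists of grayscale matrices in `[0,1]`
#'   (square, side divisible by 4).
#' @param epochs training epochs (default 150).
#' @param base_lr initial learning rate (default 2e-4).
#' @param lambda1,lambda2,lambda3 weights of the A-to-B adversarial,
#'   B-to-A adversarial, and cycle terms (defaults 1, 1, 10).
#' @param gen,disc architecture descriptions from [generator_spec()] and
#'   [discriminator_spec()].
#' @param buffer_size replay-buffer capacity for discriminator updates.
#' @param beta1 Adam first-moment decay (default 0.5).
#' @param keep_checkpoints store A-to-B generator weights after each
#'   epoch so an intermediate epoch can be selected later.
#' @param seed RNG seed; fixes initialization and data order.
#' @param verbose print per-epoch loss summaries.
#' @return an object of class `cyclegan` with the trained networks, the
#'   per-epoch loss `history`, and optional `checkpoints`.
#' @seealso [predict.cyclegan()], [synthesis_quality()],
#'   [select_intermediate()]
#' @export
fit_cyclegan <- function(domain_a, domain_b, epochs = 150L, base_lr = 2e-4,
                         lambda1 = 1, lambda2 = 1, lambda3 = 10,
                         gen = generator_spec(), disc = discriminator_spec(),
                         buffer_size = 50L, beta1 = 0.5,
                         keep_checkpoints = FALSE, seed = 1L,
                         verbose = FALSE) {
  if (any(c(lambda1, lambda2, lambda3) < 0))
    stop("loss weights must be non-negative")
  set.seed(seed)
  st <- init_cyclegan(gen, disc)
  res <- if (epochs > 0L)
    cyclegan_train_loop(st, domain_a, domain_b, epochs, base_lr,
                        lambda1, lambda2, lambda3,
                        buffer_size = buffer_size, beta1 = beta1,
                        keep_checkpoints = keep_checkpoints,
                        verbose = verbose)
  else list(history = NULL, checkpoints = list())
  structure(list(state = st, gen = gen, disc = disc,
                 history = res$history, checkpoints = res$checkpoints,
                 epochs = epochs,
                 lambda = c(lambda1, lambda2, lambda3), seed = seed),
            class = "cyclegan")
}

#' Translate images with a fitted synthesis model
#'
#' Applies a generator to grayscale images in `[0,1]`; the tanh output in
#' `[-1,1]` is rescaled back to `[0,1]`.
#'
#' @param object a `cyclegan` model.
#' @param images a matrix or list of matrices in `[0,1]`.
#' @param direction `"ab"` (source to target style, the default) or
#'   `"ba"`.
#' @param checkpoint optional epoch index into the stored checkpoints
#'   (A-to-B direction only).
#' @param ... unused.
#' @return a matrix, or list of matrices, matching the input shape.
#' @export
predict.cyclegan <- function(object, images, direction = c("ab", "ba"),
                             checkpoint = NULL, ...) {
  direction <- match.arg(direction)
  single <- is.matrix(images)
  if (single) images <- list(images)
  net <- if (direction == "ab") object$state$G_ab else object$state$G_ba
  if (!is.null(checkpoint)) {
    if (direction != "ab") stop("checkpoints are stored for the A-to-B generator")
    if (checkpoint < 1L || checkpoint > length(object$checkpoints))
      stop("no such checkpoint")
    saved <- get_params(net)
    set_params(net, object$checkpoints[[checkpoint]])
    on.exit(set_params(net, saved))
  }
  out <- lapply(images, function(im) {
    y <- mod_forward(net, nn_tensor(to_pm1(im)), train = FALSE)
    y <- from_pm1(y)
    dim(y) <- dim(im)
    pmin(pmax(y, 0), 1)
  })
  if (single) out[[1]] else out
}

#' @export
print.cyclegan <- function(x, ...) {
  cat("Cycle-consistent synthesis model\n")
  cat(sprintf("  generators: %d residual blocks, base %d channels (%s params each)\n",
              x$gen$n_res_blocks, x$gen$base_channels,
              format(n_params(x$state$G_ab), big.mark = ",")))
  cat(sprintf("  discriminators: %d stride-2 layers, base %d channels\n",
              x$disc$n_layers, x$disc$base_channels))
  cat(sprintf("  trained %d epochs, weights (%g, %g, %g), seed %d\n",
              x$epochs, x$lambda[1], x$lambda[2], x$lambda[3], x$seed))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: total %.4f, cycle %.4f\n",
                last[["total"]], last[["cycle"]]))
  }
  invisible(x)
}

#' @export
plot.cyclegan <- function(x, ...) {
  if (is.null(x$history)) stop("no training history")
  h <- x$history
  graphics::matplot(h[, "epoch"], h[, c("total", "cycle", "d_a", "d_b")],
                    type = "l", lty = 1, xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("total", "cycle", "d_a", "d_b"),
                   col = 1:4, lty = 1, bty = "n")
  invisible(x)
}

#' Synthesis quality measures
#'
#' Compares a synthetic target-style image against the source label (or
#' image) that produced it. The synthetic image is binarized by Otsu's
#' threshold; the cosine similarity between the flattened binary images
#' and the ratio of vessel-pixel proportions (synthetic over source) are
#' returned. A diameter ratio near 1 indicates that translation
#' preserved vessel caliber.
#'
#' @param reference binary source mask (or image) as a matrix.
#' @param synthetic synthetic grayscale image, same shape.
#' @return list with `cosine` and `diameter_ratio`.
#' @export
synthesis_quality <- function(reference, synthetic) {
  if (!identical(dim(reference), dim(synthetic)))
    stop("shape mismatch in synthesis_quality")
  bin <- otsu_segment(synthetic)
  a <- as.numeric(reference); b <- as.numeric(bin)
  na2 <- sum(a * a); nb2 <- sum(b * b)
  cosine <- if (na2 == 0 || nb2 == 0) {
    warning("cosine similarity undefined for an all-zero image")
    NaN
  } else sum(a * b) / sqrt(na2 * nb2)
  rr <- vessel_pixel_ratio(reference >= 0.5)
  ratio <- if (rr == 0) NaN else vessel_pixel_ratio(bin) / rr
  list(cosine = cosine, diameter_ratio = ratio)
}
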