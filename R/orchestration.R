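# Training regimes (two-stage and end-to-end), learning-rate schedule,
# dataset splitting, intermediate-epoch selection, and the
# multi-strategy experiment driver.

#' Random train/test split
#'
#' Random permutation split under a seed; the training size is
#' `round(n * train_fraction)`.
#'
#' @param n_images total image count (>= 2).
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed RNG seed.
#' @return a `dataset_split`: list with integer `train` and `test` id
#'   vectors (disjoint, covering `1:n_images`).
#' @export
split_dataset <- function(n_images, train_fraction = 0.8, seed = 1L) {
  if (n_images < 2L) stop("need at least two images to split")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly in (0, 1)")
  set.seed(seed)
  perm <- sample.int(n_images)
  n_train <- round(n_images * train_fraction)
  structure(list(train = sort(perm[seq_len(n_train)]),
                 test = sort(perm[-seq_len(n_train)]),
                 train_fraction = train_fraction),
            class = "dataset_split")
}

#' Synthesis learning-rate schedule
#'
#' Constant at `base_lr` for the first two thirds of the epochs, then
#' linearly decayed to zero at `total_epochs`. Epochs are 0-based:
#' with 150 total epochs, epochs 0-99 use the base rate and the decay
#' ramp reaches zero at epoch 150.
#'
#' @param epoch 0-based epoch index, `0 <= epoch <= total_epochs`.
#' @param total_epochs schedule length (default 150).
#' @param base_lr initial learning rate (default 2e-4).
#' @return the learning rate at `epoch`.
#' @export
lr_schedule <- function(epoch, total_epochs = 150L, base_lr = 2e-4) {
  if (any(epoch < 0)) stop("epoch must be non-negative")
  if (any(epoch > total_epochs)) stop("epoch beyond schedule")
  knee <- ceiling(2 * total_epochs / 3)
  ifelse(epoch < knee, base_lr,
         base_lr * (total_epochs - epoch) / (total_epochs - knee))
}

#' Select an intermediate synthesis epoch
#'
#' Ranks per-epoch generator checkpoints by the mean cosine similarity
#' between the binarized synthetic images and the source labels
#' ([synthesis_quality()]), returning the best epoch — an automated,
#' reproducible stand-in for visual inspection of intermediate synthetic
#' results. Mode `"last"` simply returns the final epoch. Ties break to
#' the earliest epoch.
#'
#' @param model a `cyclegan` fitted with `keep_checkpoints = TRUE` (for
#'   `"best_cosine"`).
#' @param images source images to synthesize for scoring.
#' @param labels their binary labels.
#' @param mode `"best_cosine"` (default) or `"last"`.
#' @return the selected epoch index.
#' @export
select_intermediate <- function(model, images = NULL, labels = NULL,
                                mode = c("best_cosine", "last")) {
  mode <- match.arg(mode)
  if (model$epochs < 1L) stop("model has no trained epochs")
  if (mode == "last" || length(model$checkpoints) == 0L)
    return(model$epochs)
  scores <- vapply(seq_along(model$checkpoints), function(ep) {
    syn <- predict(model, images, checkpoint = ep)
    mean(vapply(seq_along(syn), function(i) {
      q <- suppressWarnings(synthesis_quality(labels[[i]], syn[[i]]))
      if (is.nan(q$cosine)) 0 else q$cosine
    }, 1))
  }, 1)
  which.max(scores)  # first maximum: earliest epoch wins ties
}

prep_domain <- function(images, config, invert = FALSE) {
  pc <- preprocess_config(
    clahe_clip_limit = config$preprocess$clahe_clip_limit,
    clahe_tile_grid = config$preprocess$clahe_tile_grid,
    gamma = config$preprocess$gamma,
    normalization_mode = config$preprocess$normalization_mode)
  lapply(images, function(im) {
    out <- preprocess_image(im, pc)
    if (invert) 1 - out else out
  })
}

#' Fit the full domain-adaptation segmenter
#'
#' One call running a complete training strategy:
#' \describe{
#'   \item{`otsu`}{no training; prediction thresholds each image
#'     adaptively.}
#'   \item{`2step_only`, `2step_vdsm`, `2step_pssm`}{two-stage training:
#'     preprocess both domains, apply the requested size matching,
#'     extract patches, fit the synthesis model, select an intermediate
#'     epoch, synthesize speckle-style patches from the source patches,
#'     and fit the U-Net on them with the source labels.}
#'   \item{`e2e_vdsm`, `e2e_pssm`}{single joint optimization of the
#'     synthesis networks and the segmenter under the combined loss
#'     (adversarial + cycle + Dice, weights `lambda1..lambda4`); the
#'     segmentation gradient flows into the A-to-B generator but not the
#'     discriminators.}
#' }
#'
#' @param source_images,source_labels labeled source-domain images
#'   (lists of matrices).
#' @param target_images unlabeled target-domain images.
#' @param strategy one of `"otsu"`, `"2step_only"`, `"2step_vdsm"`,
#'   `"2step_pssm"`, `"e2e_vdsm"`, `"e2e_pssm"`.
#' @param config a configuration list from [default_config()] or
#'   [tiny_config()].
#' @param seed RNG seed for every stage.
#' @param verbose print stage progress.
#' @return an object of class `lsci_adapt` holding the fitted synthesis
#'   model (`cyclegan`), segmenter (`unet`), the strategy, and the
#'   configuration.
#' @seealso [predict.lsci_adapt()], [run_experiment()]
#' @export
lsci_adapt <- function(source_images, source_labels, target_images,
                       strategy = c("2step_vdsm", "otsu", "2step_only",
                                    "2step_pssm", "e2e_vdsm", "e2e_pssm"),
                       config = default_config(), seed = 1L,
                       verbose = FALSE) {
  strategy <- match.arg(strategy)
  out <- structure(list(strategy = strategy, config = config, seed = seed,
                        cyclegan = NULL, unet = NULL),
                   class = "lsci_adapt")
  if (strategy == "otsu") return(out)

  say <- function(...) if (verbose) message(sprintf(...))
  say("preprocessing %d source / %d target images",
      length(source_images), length(target_images))
  src <- prep_domain(source_images, config,
                     invert = config$preprocess$invert_source)
  tgt <- prep_domain(target_images, config, invert = FALSE)
  labs <- lapply(source_labels, function(m) (m > 0.5) * 1)

  use_vdsm <- grepl("vdsm", strategy)
  use_pssm <- grepl("pssm", strategy)
  if (use_vdsm) {
    say("size matching by vessel dilation")
    for (i in seq_along(src)) {
      sm <- apply_vdsm(src[[i]], labs[[i]])
      src[[i]] <- sm$image; labs[[i]] <- sm$label
    }
  }

  ps <- config$patch$size
  say("extracting %d source and %d target patches of %dx%d",
      config$patch$n_source, config$patch$n_target, ps, ps)
  src_patches <- extract_training_patches(src, labs, config$patch$n_source,
                                          ps, seed = seed)
  tgt_patches <- extract_training_patches(tgt, NULL, config$patch$n_target,
                                          ps, seed = seed + 1L)
  if (use_pssm) {
    src_patches <- select_patches(src_patches, th = config$size_match$th)
    say("psSM kept %d source patches", length(src_patches))
    if (!length(src_patches))
      stop("psSM removed every source patch; lower th or use denser sources")
  }
  a_imgs <- lapply(src_patches, `[[`, "image")
  a_labs <- lapply(src_patches, `[[`, "label")
  b_imgs <- lapply(tgt_patches, `[[`, "image")

  syn <- config$synthesis; seg <- config$segmentation
  gen <- generator_spec(syn$n_res_blocks, syn$base_channels)
  disc <- discriminator_spec(syn$disc_layers, syn$base_channels)
  uspec <- unet_spec(seg$depth, seg$base_channels, seg$dropout,
                     seg$batchnorm)

  if (grepl("^e2e", strategy)) {
    say("end-to-end joint training, %d epochs", config$e2e$epochs)
    unet <- build_unet(uspec, seed = seed + 2L)
    # seed after the segmenter is built: with lambda4 = 0 the joint loop
    # then reproduces the two-stage synthesis losses exactly
    set.seed(seed)
    st <- init_cyclegan(gen, disc)
    res <- cyclegan_train_loop(
      st, a_imgs, b_imgs, epochs = config$e2e$epochs,
      base_lr = config$e2e$lr,
      lambda1 = syn$lambda1, lambda2 = syn$lambda2, lambda3 = syn$lambda3,
      lambda4 = config$e2e$lambda4, unet = unet, a_labels = a_labs,
      buffer_size = syn$buffer_size, beta1 = syn$beta1, verbose = verbose)
    out$cyclegan <- structure(
      list(state = st, gen = gen, disc = disc, history = res$history,
           checkpoints = list(), epochs = config$e2e$epochs,
           lambda = c(syn$lambda1, syn$lambda2, syn$lambda3), seed = seed),
      class = "cyclegan")
    unet$input_size <- ps
    unet$trained_epochs <- config$e2e$epochs
    unet$history <- res$history[, "dice"]
    out$unet <- unet
    return(out)
  }

  say("stage 1: synthesis training, %d epochs", syn$epochs)
  cg <- fit_cyclegan(a_imgs, b_imgs, epochs = syn$epochs,
                     base_lr = syn$lr,
                     lambda1 = syn$lambda1, lambda2 = syn$lambda2,
                     lambda3 = syn$lambda3, gen = gen, disc = disc,
                     buffer_size = syn$buffer_size, beta1 = syn$beta1,
                     keep_checkpoints = syn$keep_checkpoints,
                     seed = seed, verbose = verbose)
  ep <- select_intermediate(cg, a_imgs, a_labs,
                            mode = config$select_mode)
  say("selected synthesis epoch %d/%d", ep, cg$epochs)
  ckpt <- if (length(cg$checkpoints)) ep else NULL
  synth <- predict(cg, a_imgs, checkpoint = ckpt)

  say("stage 2: segmentation training, %d epochs", seg$epochs)
  un <- fit_unet(synth, a_labs, epochs = seg$epochs, lr = seg$lr,
                 batch_size = seg$batch_size, spec = uspec,
                 seed = seed + 2L, verbose = verbose)
  out$cyclegan <- cg
  out$selected_epoch <- ep
  out$unet <- un
  out
}

#' Segment new target-domain images
#'
#' For learned strategies, preprocesses each image and runs the tiled
#' U-Net inference; for the `otsu` strategy, preprocesses and applies
#' the adaptive threshold.
#'
#' @param object a fitted `lsci_adapt` model.
#' @param newdata matrix or list of matrices in `[0,1]`.
#' @param type `"mask"` (default) or `"prob"` (learned strategies only).
#' @param ... unused.
#' @return binary mask (or probability map), or list thereof.
#' @export
predict.lsci_adapt <- function(object, newdata, type = c("mask", "prob"),
                               ...) {
  type <- match.arg(type)
  single <- is.matrix(newdata)
  if (single) newdata <- list(newdata)
  imgs <- prep_domain(newdata, object$config, invert = FALSE)
  out <- if (object$strategy == "otsu") {
    if (type == "prob") stop("the otsu strategy produces no probabilities")
    lapply(imgs, otsu_segment)
  } else {
    lapply(imgs, function(im)
      predict(object$unet, im, type = type,
              threshold = object$config$segmentation$threshold,
              tile = object$config$patch$tile))
  }
  if (single) out[[1]] else out
}

#' @export
print.lsci_adapt <- function(x, ...) {
  cat("Domain-adaptation vessel segmenter\n")
  cat(sprintf("  strategy: %s, seed %d\n", x$strategy, x$seed))
  if (!is.null(x$cyclegan)) print(x$cyclegan)
  if (!is.null(x$unet)) print(x$unet)
  invisible(x)
}

#' Run and evaluate several training strategies
#'
#' Fits each strategy on the same data, segments the held-out labeled
#' target images, and tabulates the four confusion-matrix metrics per
#' image, aggregated as mean +/- SEM per strategy — one report row per
#' strategy per test image.
#'
#' @param data list with `source` (`images`, `labels`), `target`
#'   (`images`), `test` (`images`, `labels`) — see [make_domain_pair()].
#' @param strategies character vector of strategy names.
#' @param config configuration list.
#' @param seed RNG seed.
#' @param verbose print progress.
#' @return a `metrics_report` with an extra `models` attribute.
#' @export
run_experiment <- function(data,
                           strategies = c("otsu", "2step_only",
                                          "2step_vdsm"),
                           config = tiny_config(), seed = 1L,
                           verbose = FALSE) {
  models <- list(); rows <- list()
  for (st in strategies) {
    if (verbose) message("=== strategy ", st)
    fit <- lsci_adapt(data$source$images, data$source$labels,
                      data$target$images, strategy = st, config = config,
                      seed = seed, verbose = verbose)
    preds <- predict(fit, data$test$images)
    for (i in seq_along(preds)) {
      m <- segmentation_metrics(confusion_counts(preds[[i]],
                                                 data$test$labels[[i]]))
      rows[[length(rows) + 1L]] <-
        data.frame(strategy = st, image_id = i, t(m))
    }
    models[[st]] <- fit
  }
  rep <- aggregate_report(do.call(rbind, rows))
  attr(rep, "models") <- models
  rep
}
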