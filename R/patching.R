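# Patch extraction for training augmentation and the
# tile -> upsample -> segment -> downsample -> reassemble inference
# scheme.

reflect_pad <- function(img, bottom, right) {
  if (bottom > 0) {
    n <- nrow(img)
    img <- rbind(img, img[n - seq_len(bottom), , drop = FALSE])
  }
  if (right > 0) {
    m <- ncol(img)
    img <- cbind(img, img[, m - seq_len(right), drop = FALSE])
  }
  img
}

#' Extract random training patches
#'
#' Draws `n_patches` square crops with origins uniform over all valid
#' positions across all images (each image weighted by its number of
#' valid origins), reproducibly under `seed`. Labels, when given, are
#' cropped congruently. Images smaller than the patch in either
#' dimension are reflection-padded first.
#'
#' @param images list of grayscale matrices.
#' @param labels optional list of congruent binary masks.
#' @param n_patches number of patches to draw (default 640).
#' @param patch_size square patch side (default 256).
#' @param seed RNG seed.
#' @return list of patches: each `list(image, label, origin, source_id)`
#'   with 1-based origin in the (padded) source frame.
#' @export
extract_training_patches <- function(images, labels = NULL,
                                     n_patches = 640L, patch_size = 256L,
                                     seed = 1L) {
  if (n_patches <= 0L) stop("n_patches must be positive")
  if (!is.null(labels) && length(labels) != length(images))
    stop("labels must pair with images")
  set.seed(seed)
  prep <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    pb <- max(0L, patch_size - nrow(img)); pr <- max(0L, patch_size - ncol(img))
    list(image = reflect_pad(img, pb, pr),
         label = if (!is.null(labels)) reflect_pad(labels[[i]], pb, pr))
  })
  nvalid <- vapply(prep, function(p)
    (nrow(p$image) - patch_size + 1) * (ncol(p$image) - patch_size + 1), 1)
  pick <- sample.int(length(images), n_patches, replace = TRUE,
                     prob = nvalid / sum(nvalid))
  lapply(seq_len(n_patches), function(j) {
    i <- pick[j]; p <- prep[[i]]
    r <- sample.int(nrow(p$image) - patch_size + 1L, 1L)
    cc <- sample.int(ncol(p$image) - patch_size + 1L, 1L)
    rows <- r:(r + patch_size - 1L); cols <- cc:(cc + patch_size - 1L)
    list(image = p$image[rows, cols],
         label = if (!is.null(p$label)) p$label[rows, cols],
         origin = c(r, cc), source_id = i)
  })
}

#' Cut an image into a non-overlapping tile grid
#'
#' Tiles of side `tile` covering the whole image; dimensions not
#' divisible by `tile` are reflection-padded on the bottom/right to the
#' next multiple, and the returned plan records the padding so
#' [reassemble()] can undo it exactly.
#'
#' @param img grayscale matrix.
#' @param tile tile side (default 80).
#' @return list with `patches` (each `list(pixels, origin)`) and `plan`
#'   (a `tile_plan`: source shape, tile size, origins, padding).
#' @export
tile_image <- function(img, tile = 80L) {
  if (tile < 1L) stop("tile must be >= 1")
  d <- dim(img)
  ph <- ceiling(d[1] / tile) * tile - d[1]
  pw <- ceiling(d[2] / tile) * tile - d[2]
  pad <- reflect_pad(img, ph, pw)
  orows <- seq(1L, nrow(pad), by = tile)
  ocols <- seq(1L, ncol(pad), by = tile)
  origins <- as.matrix(expand.grid(row = orows, col = ocols))
  patches <- lapply(seq_len(nrow(origins)), function(k) {
    r <- origins[k, 1]; cc <- origins[k, 2]
    list(pixels = pad[r:(r + tile - 1L), cc:(cc + tile - 1L)],
         origin = c(r, cc))
  })
  plan <- structure(list(source_shape = d, tile = as.integer(tile),
                         origins = origins, padding = c(ph, pw),
                         pad_mode = "reflect"),
                    class = "tile_plan")
  list(patches = patches, plan = plan)
}

#' Resample a patch
#'
#' Bilinear interpolation for intensity or probability patches, nearest
#' neighbour for hard masks (which therefore stay binary).
#'
#' @param patch matrix to resample.
#' @param to_size target square side.
#' @param kind `"image_bilinear"` (default) or `"mask_nearest"`.
#' @return resampled `to_size x to_size` matrix.
#' @export
resample_patch <- function(patch, to_size,
                           kind = c("image_bilinear", "mask_nearest")) {
  kind <- match.arg(kind)
  if (to_size < 1L) stop("to_size must be >= 1")
  if (nrow(patch) == to_size && ncol(patch) == to_size) return(patch)
  filt <- if (kind == "image_bilinear") "bilinear" else "none"
  out <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(patch)),
                                              w = to_size, h = to_size,
                                              filter = filt)))
  if (kind == "mask_nearest") (out > 0.5) * 1 else out
}

#' Reassemble tiles into the source image
#'
#' Inverse of [tile_image()], including removal of the recorded
#' padding; patch order is irrelevant because each patch carries its
#' origin. Exact (no resampling).
#'
#' @param patches list of `list(pixels, origin)` tiles.
#' @param plan the `tile_plan` from [tile_image()].
#' @return the reconstructed matrix with the plan's source shape.
#' @export
reassemble <- function(patches, plan) {
  if (!inherits(plan, "tile_plan")) stop("plan must be a tile_plan")
  if (length(patches) != nrow(plan$origins))
    stop("patch count does not match the plan")
  t <- plan$tile
  full <- matrix(NA_real_, plan$source_shape[1] + plan$padding[1],
                 plan$source_shape[2] + plan$padding[2])
  seen <- character(0)
  for (p in patches) {
    key <- paste(p$origin, collapse = ",")
    if (!key %in% apply(plan$origins, 1, paste, collapse = ","))
      stop("patch origin not in plan")
    if (key %in% seen) stop("duplicate patch origin")
    seen <- c(seen, key)
    full[p$origin[1]:(p$origin[1] + t - 1L),
         p$origin[2]:(p$origin[2] + t - 1L)] <- p$pixels
  }
  if (anyNA(full)) stop("missing tiles: plan not covered")
  full[seq_len(plan$source_shape[1]), seq_len(plan$source_shape[2])]
}
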