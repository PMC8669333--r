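# Image I/O and the preprocessing chain applied to both domains:
# grayscale conversion, normalization, CLAHE, gamma correction.
# Images are plain numeric matrices in [0,1] (rows = image rows); binary
# masks are matrices over {0,1}.

check_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) stop("expected a numeric matrix")
  if (!all(is.finite(img))) stop("image contains non-finite values")
  invisible(img)
}

#' Convert an RGB raster to grayscale
#'
#' Luminance-weighted combination (ITU-R BT.601 weights 0.299, 0.587,
#' 0.114) of a 3-channel array with values in `[0,1]`.
#'
#' @param rgb a `height x width x 3` numeric array.
#' @return a grayscale matrix in `[0,1]`.
#' @export
to_grayscale <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L)
    stop("to_grayscale expects a height x width x 3 array")
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Normalize image intensities
#'
#' `minmax` rescales to span `[0,1]`; a constant image maps to all
#' zeros (documented convention, not an error). `zscore_then_clip`
#' standardizes then maps mean +/- 3 sd onto `[0,1]` with clipping.
#'
#' @param img grayscale matrix.
#' @param mode `"minmax"` (default) or `"zscore_then_clip"`.
#' @return normalized matrix in `[0,1]`, same shape.
#' @export
normalize_gray <- function(img, mode = c("minmax", "zscore_then_clip")) {
  mode <- match.arg(mode)
  check_gray(img)
  if (mode == "minmax") {
    r <- range(img)
    if (r[1] == r[2]) return(img * 0)
    (img - r[1]) / (r[2] - r[1])
  } else {
    s <- stats::sd(img)
    if (s == 0) return(img * 0)
    z <- (img - mean(img)) / s
    pmin(pmax((z + 3) / 6, 0), 1)
  }
}

#' Contrast-limited adaptive histogram equalization
#'
#' Per-tile clipped histogram equalization with bilinear blending
#' between tiles (delegated to `EBImage::clahe`).
#'
#' @param img grayscale matrix in `[0,1]`.
#' @param clip_limit contrast limit on the 8-bit-equivalent scale
#'   (default 2).
#' @param tile_grid integer `(rows, cols)` tile grid (default `c(8, 8)`).
#' @return equalized matrix in `[0,1]`.
#' @export
clahe_equalize <- function(img, clip_limit = 2, tile_grid = c(8L, 8L)) {
  check_gray(img)
  if (any(tile_grid < 1L)) stop("tile grid dimensions must be >= 1")
  if (nrow(img) < tile_grid[1] || ncol(img) < tile_grid[2])
    stop("tile grid larger than the image")
  if (diff(range(img)) == 0) return(img)  # nothing to equalize
  # EBImage works column-major (x = width); transpose in and out
  y <- EBImage::clahe(EBImage::Image(t(img)), nx = tile_grid[2],
                      ny = tile_grid[1], limit = clip_limit,
                      keep.range = FALSE)
  out <- t(EBImage::imageData(y))
  pmin(pmax(out, 0), 1)
}

#' Gamma correction
#'
#' Pointwise `x^gamma` on intensities in `[0,1]`.
#'
#' @param img grayscale matrix in `[0,1]`.
#' @param gamma positive exponent; `gamma = 1` is the identity,
#'   `gamma > 1` darkens midtones.
#' @return corrected matrix.
#' @export
gamma_correct <- function(img, gamma) {
  check_gray(img)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar")
  img^gamma
}

#' Preprocessing configuration
#'
#' @param clahe_clip_limit CLAHE contrast limit; `NA` disables CLAHE.
#' @param clahe_tile_grid CLAHE tile grid `(rows, cols)`.
#' @param gamma gamma-correction exponent (> 0).
#' @param normalization_mode passed to [normalize_gray()].
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(clahe_clip_limit = 2,
                              clahe_tile_grid = c(8L, 8L),
                              gamma = 1.2,
                              normalization_mode = "minmax") {
  stopifnot(gamma > 0, all(clahe_tile_grid >= 1L))
  structure(list(clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 gamma = gamma,
                 normalization_mode = normalization_mode),
            class = "preprocess_config")
}

#' Preprocess a raw image
#'
#' Applies, in order: grayscale conversion (if RGB), min-max
#' normalization, CLAHE, gamma correction. Output is guaranteed to lie
#' in `[0,1]`. The chain is not idempotent (CLAHE redistributes
#' intensities each time).
#'
#' @param raw a grayscale matrix or `height x width x 3` RGB array.
#' @param config a [preprocess_config()].
#' @return a grayscale matrix in `[0,1]`.
#' @export
preprocess_image <- function(raw, config = preprocess_config()) {
  img <- if (length(dim(raw)) == 3L) to_grayscale(raw) else raw
  img <- normalize_gray(img, config$normalization_mode)
  if (!is.na(config$clahe_clip_limit))
    img <- clahe_equalize(img, config$clahe_clip_limit, config$clahe_tile_grid)
  gamma_correct(img, config$gamma)
}

#' Read a grayscale image
#'
#' Reads PNG or TIFF (by extension); 8- or 16-bit integer data are
#' rescaled by the maximum code value; RGB inputs are converted by
#' [to_grayscale()].
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return a grayscale matrix in `[0,1]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  d <- dim(x)
  if (length(d) == 3L) {
    if (d[3] >= 3L) x <- to_grayscale(x[, , 1:3, drop = FALSE])
    else x <- x[, , 1]
  }
  x
}

#' Write a grayscale image
#'
#' @param img matrix in `[0,1]`.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @export
write_gray_image <- function(img, path) {
  check_gray(img)
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' Read a binary mask
#'
#' Reads a PNG/TIFF mask stored with foreground as high values;
#' intensities above 0.5 map to 1.
#'
#' @param path file path.
#' @return a matrix over `{0, 1}`.
#' @export
read_mask <- function(path) (read_gray_image(path) > 0.5) * 1

#' Write a binary mask
#'
#' Stored as PNG/TIFF with `{0,1}` mapped to `{0, max code}`.
#'
#' @param mask matrix over `{0, 1}`.
#' @param path output path.
#' @export
write_mask <- function(mask, path) write_gray_image((mask > 0.5) * 1, path)
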