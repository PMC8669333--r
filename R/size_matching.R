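# Vessel-caliber size matching between the thin-vesseled source domain
# and the thick-vesseled target domain: morphological dilation (vdSM)
# and vessel-density patch selection (psSM).

#' The 3x3 cross structuring element
#'
#' The connectivity-1 structuring element used for vessel dilation: a
#' plus-shaped support with five active cells and anchor at the center.
#'
#' @return a `structuring_element`: list with binary `support` matrix and
#'   `anchor` (row, col).
#' @export
cross_kernel <- function() {
  structure(list(support = matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3),
                 anchor = c(2L, 2L)),
            class = "structuring_element")
}

kernel_support <- function(k) {
  if (inherits(k, "structuring_element")) k$support
  else if (is.matrix(k)) k
  else stop("expected a structuring element or binary matrix")
}

#' Binary morphological dilation
#'
#' Set union of the mask's translates by each active kernel offset
#' (translates clipped to the image frame), thickening vessels by the
#' kernel's reach.
#'
#' @param mask binary matrix.
#' @param k structuring element (default the [cross_kernel()]).
#' @return dilated binary matrix, a superset of `mask`.
#' @export
dilate_mask <- function(mask, k = cross_kernel()) {
  ks <- kernel_support(k)
  if (sum(ks) == 0) stop("empty structuring element")
  mask <- (mask > 0.5) * 1
  out <- EBImage::imageData(EBImage::dilate(EBImage::Image(t(mask)), t(ks)))
  (t(out) > 0.5) * 1
}

#' Grayscale (flat) dilation
#'
#' Each output pixel is the maximum of the input over the kernel
#' support, thickening the bright phase. Vessels must therefore be the
#' high-intensity phase; dark-vesseled source images are inverted
#' upstream.
#'
#' @param img grayscale matrix in `[0,1]`.
#' @param k structuring element (default the [cross_kernel()]).
#' @return dilated matrix, pointwise `>=` the input.
#' @export
dilate_gray <- function(img, k = cross_kernel()) {
  ks <- kernel_support(k)
  if (sum(ks) == 0) stop("empty structuring element")
  check_gray(img)
  t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(img)), t(ks))))
}

#' Vessel-pixel ratio
#'
#' Fraction of foreground pixels: count of ones over the total pixel
#' count.
#'
#' @param mask binary matrix (logical or 0/1 numeric).
#' @return a scalar in `[0,1]`.
#' @export
vessel_pixel_ratio <- function(mask) {
  if (length(mask) == 0L) stop("empty mask")
  sum(mask > 0.5) / length(mask)
}

#' Patch-selection size matching
#'
#' Keeps exactly those (patch, label) pairs whose label's vessel-pixel
#' ratio strictly exceeds the threshold, in their original order. With
#' the default `th = 0.13` this retains patches dominated by thick
#' vessels.
#'
#' @param patches list of pairs, each `list(image =, label =)` with
#'   congruent matrices (as produced by [extract_training_patches()]).
#' @param th vessel-pixel-ratio threshold, strictly exceeded to keep
#'   (default 0.13).
#' @return the filtered sublist.
#' @export
select_patches <- function(patches, th = 0.13) {
  if (!(th > 0 && th < 1)) stop("th must lie strictly in (0, 1)")
  keep <- vapply(patches, function(p) {
    if (is.null(p$label) || !identical(dim(p$image), dim(p$label)))
      stop("every patch must carry a congruent label mask")
    vessel_pixel_ratio(p$label) > th
  }, logical(1))
  patches[keep]
}

#' Vessel-dilation size matching
#'
#' Applies one pass of grayscale dilation to a (vessel-bright) source
#' image and binary dilation to its label, with the 3x3 cross kernel,
#' enlarging vessel diameter by one pixel on each side.
#'
#' @param img grayscale matrix (vessel-bright convention).
#' @param label binary label mask.
#' @param k structuring element (default [cross_kernel()]).
#' @return list with dilated `image` and `label`.
#' @export
apply_vdsm <- function(img, label, k = cross_kernel()) {
  list(image = dilate_gray(img, k), label = dilate_mask(label, k))
}
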