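# Seeded synthetic vessel-image generator for both domains, so every
# pipeline stage trains and tests without any dataset download.
#
# Vessel trees are random branching walks rasterized with per-branch
# widths. Rendering places vessels and background at configurable
# intensity levels, adds an illumination gradient and Gaussian blur,
# and (for speckle-style images) multiplicative gamma-distributed noise
# whose relative sd is 1/sqrt(shape) — a statistical stand-in for
# coherent speckle, not a physical simulation.

#' Vessel-tree generation parameters
#'
#' @param size square image side in pixels.
#' @param n_roots number of independent trees.
#' @param branch_prob probability of spawning a side branch per step.
#' @param step_len walk step length in pixels.
#' @param width_range inclusive range of vessel widths in pixels.
#' @param tortuosity sd of the per-step heading jitter (radians).
#' @return a `vessel_tree_params` list.
#' @export
vessel_tree_params <- function(size = 64L, n_roots = 2L, branch_prob = 0.06,
                               step_len = 2, width_range = c(2, 4),
                               tortuosity = 0.25) {
  stopifnot(size >= 1L, all(width_range >= 1), branch_prob >= 0,
            branch_prob <= 1)
  structure(list(size = as.integer(size), n_roots = n_roots,
                 branch_prob = branch_prob, step_len = step_len,
                 width_range = width_range, tortuosity = tortuosity),
            class = "vessel_tree_params")
}

draw_disk <- function(mask, r, c, radius) {
  n <- nrow(mask); m <- ncol(mask)
  ir <- max(1, floor(r - radius)):min(n, ceiling(r + radius))
  ic <- max(1, floor(c - radius)):min(m, ceiling(c + radius))
  if (!length(ir) || !length(ic)) return(mask)
  dd <- outer((ir - r)^2, (ic - c)^2, `+`)
  mask[ir, ic][dd <= radius^2] <- 1
  mask
}

#' Generate a random vessel-tree mask
#'
#' Random branching walks from the image border inward, rasterized as
#' disks of half the branch width along the path. Reproducible under
#' `seed`; each tree is connected by construction.
#'
#' @param params a [vessel_tree_params()].
#' @param seed RNG seed.
#' @return a binary matrix of the requested size.
#' @export
generate_vessel_tree <- function(params = vessel_tree_params(), seed = 1L) {
  if (params$size < 1L) stop("image size must be positive")
  set.seed(seed)
  n <- params$size
  mask <- matrix(0, n, n)
  if (params$n_roots < 1) return(mask)
  max_steps <- ceiling(4 * n / params$step_len)
  for (root in seq_len(params$n_roots)) {
    side <- sample.int(4L, 1L)
    pos <- switch(side,
      c(1, stats::runif(1, 1, n)), c(n, stats::runif(1, 1, n)),
      c(stats::runif(1, 1, n), 1), c(stats::runif(1, 1, n), n))
    heading <- atan2(n / 2 - pos[1], n / 2 - pos[2]) +
      stats::rnorm(1, 0, 0.3)
    width <- stats::runif(1, params$width_range[1], params$width_range[2])
    stack <- list(list(pos = pos, heading = heading, width = width,
                       steps = max_steps))
    while (length(stack)) {
      br <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      pos <- br$pos; heading <- br$heading; width <- br$width
      for (s in seq_len(br$steps)) {
        mask <- draw_disk(mask, pos[1], pos[2], width / 2)
        heading <- heading + stats::rnorm(1, 0, params$tortuosity)
        pos <- pos + params$step_len * c(sin(heading), cos(heading))
        if (pos[1] < 1 || pos[1] > n || pos[2] < 1 || pos[2] > n) break
        if (stats::runif(1) < params$branch_prob) {
          child_w <- max(params$width_range[1], width * stats::runif(1, 0.6, 0.9))
          stack[[length(stack) + 1L]] <- list(
            pos = pos,
            heading = heading + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 1.1),
            width = child_w, steps = max(2L, br$steps %/% 2L))
        }
      }
    }
  }
  mask
}

#' Rendering parameters
#'
#' @param domain `"fundus_like"` (dark thin vessels on a bright
#'   background, no speckle) or `"lsci_like"` (bright thick vessels,
#'   multiplicative speckle-style noise, stronger illumination
#'   non-uniformity).
#' @param vessel_level,background_level intensities in `[0,1]`.
#' @param gradient_amplitude peak-to-peak amplitude of a linear
#'   illumination ramp in a random direction.
#' @param speckle_shape gamma shape of the multiplicative noise
#'   (relative sd `1/sqrt(shape)`); `NA` disables it.
#' @param blur_sigma Gaussian blur sd in pixels; 0 disables.
#' @return a `render_params` list.
#' @export
render_params <- function(domain = c("fundus_like", "lsci_like"),
                          vessel_level = NULL, background_level = NULL,
                          gradient_amplitude = NULL, speckle_shape = NULL,
                          blur_sigma = NULL) {
  domain <- match.arg(domain)
  d <- if (domain == "fundus_like")
    list(vessel_level = 0.25, background_level = 0.75,
         gradient_amplitude = 0.10, speckle_shape = NA_real_,
         blur_sigma = 0.6)
  else
    list(vessel_level = 0.75, background_level = 0.30,
         gradient_amplitude = 0.20, speckle_shape = 25,
         blur_sigma = 0.8)
  for (nm in names(d)) {
    v <- get(nm)
    if (!is.null(v)) d[[nm]] <- v
  }
  if (!is.na(d$speckle_shape) && d$speckle_shape <= 0)
    stop("speckle shape must be positive")
  structure(c(list(domain = domain), d), class = "render_params")
}

#' Render a vessel mask as a grayscale image
#'
#' Two-level image (vessel/background), optionally with a linear
#' illumination gradient, Gaussian blur, and multiplicative
#' gamma-distributed speckle-style noise; clipped to `[0,1]`.
#'
#' @param mask binary vessel mask.
#' @param params a [render_params()].
#' @param seed RNG seed (gradient direction and noise).
#' @return a grayscale matrix in `[0,1]`.
#' @export
render_vessel_image <- function(mask, params = render_params("lsci_like"),
                                seed = 1L) {
  set.seed(seed)
  n <- nrow(mask); m <- ncol(mask)
  img <- params$background_level +
    (params$vessel_level - params$background_level) * (mask > 0.5)
  if (params$gradient_amplitude > 0) {
    th <- stats::runif(1, 0, 2 * pi)
    ramp <- outer(seq_len(n) / n * sin(th), seq_len(m) / m * cos(th), `+`)
    ramp <- if (diff(range(ramp)) > 0)
      (ramp - min(ramp)) / diff(range(ramp)) else ramp * 0
    img <- img + params$gradient_amplitude * (ramp - 0.5)
  }
  if (params$blur_sigma > 0)
    img <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)),
                                               sigma = params$blur_sigma)))
  if (!is.na(params$speckle_shape)) {
    k <- params$speckle_shape
    img <- img * matrix(stats::rgamma(n * m, shape = k, rate = k), n, m)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate paired source/target fixture domains
#'
#' Emulates the study's data layout: a labeled source set rendered
#' fundus-like with thin vessels (widths 1-3 px) and an unlabeled
#' target set rendered speckle-like with thick vessels (widths 4-9 px),
#' reproducing the vessel-caliber mismatch the size-matching strategies
#' address. Target labels are returned separately, for evaluation only.
#'
#' @param n_source,n_target image counts.
#' @param size square image side (default 64).
#' @param seed RNG seed; per-image seeds are derived from it.
#' @return list with `source` (`images`, `labels`), `target`
#'   (`images`), and `target_labels`.
#' @export
make_domain_pair <- function(n_source = 12L, n_target = 12L, size = 64L,
                             seed = 1L) {
  if (n_source < 1L || n_target < 1L) stop("counts must be >= 1")
  src_par <- vessel_tree_params(size = size, n_roots = 3L,
                                width_range = c(1, 3), branch_prob = 0.10,
                                tortuosity = 0.30)
  tgt_par <- vessel_tree_params(size = size, n_roots = 2L,
                                width_range = c(4, 9), branch_prob = 0.05,
                                tortuosity = 0.20)
  src_lab <- lapply(seq_len(n_source), function(i)
    generate_vessel_tree(src_par, seed = seed * 1000L + i))
  src_img <- lapply(seq_len(n_source), function(i)
    render_vessel_image(src_lab[[i]], render_params("fundus_like"),
                        seed = seed * 1000L + 500L + i))
  tgt_lab <- lapply(seq_len(n_target), function(i)
    generate_vessel_tree(tgt_par, seed = seed * 2000L + i))
  tgt_img <- lapply(seq_len(n_target), function(i)
    render_vessel_image(tgt_lab[[i]], render_params("lsci_like"),
                        seed = seed * 2000L + 500L + i))
  list(source = list(images = src_img, labels = src_lab),
       target = list(images = tgt_img),
       target_labels = tgt_lab)
}

#' Generate a labeled speckle-style fixture set
#'
#' Convenience wrapper producing `n` speckle-like images with their
#' masks (thick vessels), e.g. for supervised sanity training.
#'
#' @param n image count.
#' @param size square image side.
#' @param seed RNG seed.
#' @return list with `images` and `labels`.
#' @export
make_lsci_set <- function(n, size = 64L, seed = 1L) {
  par <- vessel_tree_params(size = size, n_roots = 2L,
                            width_range = c(4, 9), branch_prob = 0.05,
                            tortuosity = 0.20)
  labels <- lapply(seq_len(n), function(i)
    generate_vessel_tree(par, seed = seed * 3000L + i))
  images <- lapply(seq_len(n), function(i)
    render_vessel_image(labels[[i]], render_params("lsci_like"),
                        seed = seed * 3000L + 500L + i))
  list(images = images, labels = labels)
}

#' Estimate the vessel width of a mask
#'
#' Distance-transform caliber estimate: `2 * d - 1` evaluated at the
#' upper quartile of the distance-to-background over ridge pixels
#' (foreground local maxima of the Euclidean distance transform). The
#' upper quartile reads through the staircase pinches that rasterized
#' oblique branches produce, where the mean would under-read; the
#' `2d - 1` mapping is exact for axis-aligned bars of odd width.
#'
#' @param mask binary matrix.
#' @return estimated dominant width in pixels (`NaN` for an empty mask).
#' @export
mean_vessel_width <- function(mask) {
  if (sum(mask) == 0) return(NaN)
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(t(mask))))
  dm <- t(dm)
  mx <- dilate_gray(dm / max(dm)) * max(dm)  # 4-neighbour local maxima
  ridge <- mask > 0.5 & dm >= mx - 1e-9
  2 * stats::quantile(dm[ridge], 0.75, names = FALSE) - 1
}
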