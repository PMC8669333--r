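# Otsu-threshold baseline, confusion-matrix metrics, majority-vote
# ground truth, and mean +/- SEM report aggregation.

#' Otsu's threshold
#'
#' Histogram-based threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over `n_bins` equal-width bins on `[0,1]`.
#' The returned value is the upper boundary of the chosen bin; ties are
#' broken towards the lowest threshold. A constant image returns its
#' single value (foreground then empty under strict `>`).
#'
#' @param img grayscale matrix in `[0,1]`.
#' @param n_bins histogram bins (default 256).
#' @return the threshold, a scalar in `[0,1]`.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  check_gray(img)
  if (diff(range(img)) == 0) return(img[1])
  bin <- pmin(floor(as.numeric(img) * n_bins), n_bins - 1L)
  h <- tabulate(bin + 1L, nbins = n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[n_bins]
  w1 <- 1 - w0
  # between-class variance for a cut after bin t (t = 1..n_bins-1)
  valid <- seq_len(n_bins - 1L)
  num <- (mt * w0[valid] - m0[valid])^2
  den <- w0[valid] * w1[valid]
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  t_star <- which.max(sigma_b)  # which.max takes the first (lowest) maximum
  t_star / n_bins
}

#' Otsu baseline segmentation
#'
#' Thresholds an image at [otsu_threshold()]; pixels strictly above the
#' threshold become foreground (vessel-bright convention). Set
#' `invert = TRUE` for vessel-dark images.
#'
#' @param img grayscale matrix in `[0,1]`.
#' @param n_bins histogram bins.
#' @param invert invert the image before thresholding.
#' @return a binary matrix.
#' @export
otsu_segment <- function(img, n_bins = 256L, invert = FALSE) {
  if (invert) img <- 1 - img
  (img > otsu_threshold(img, n_bins)) * 1
}

#' Pixel-wise confusion counts
#'
#' @param pred,gt binary matrices of the same shape.
#' @return list with `TP`, `FP`, `TN`, `FN` (summing to the pixel count).
#' @export
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch")
  p <- pred > 0.5; g <- gt > 0.5
  list(TP = sum(p & g), FP = sum(p & !g), TN = sum(!p & !g),
       FN = sum(!p & g))
}

#' Segmentation metrics from confusion counts
#'
#' `DSC = 2TP / (FP + 2TP + FN)`, `precision = TP / (TP + FP)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#' Ratios with a zero denominator are reported as `NaN`.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (from
#'   [confusion_counts()]).
#' @return named numeric vector `(DSC, precision, sensitivity,
#'   specificity)`.
#' @export
segmentation_metrics <- function(counts) {
  sdiv <- function(num, den) if (den == 0) NaN else num / den
  with(counts, c(
    DSC = sdiv(2 * TP, FP + 2 * TP + FN),
    precision = sdiv(TP, TP + FP),
    sensitivity = sdiv(TP, TP + FN),
    specificity = sdiv(TN, TN + FP)))
}

#' Majority-vote ground truth
#'
#' Pixelwise consensus of several annotators' masks: a pixel is
#' foreground iff strictly more than half of the annotators marked it
#' (even-count ties resolve to background).
#'
#' @param masks list of at least two congruent binary matrices.
#' @return the consensus binary matrix.
#' @export
majority_vote <- function(masks) {
  if (length(masks) < 2L) stop("need at least two annotator masks")
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d)) stop("mask shapes differ")
  votes <- Reduce(`+`, lapply(masks, function(m) (m > 0.5) * 1))
  (votes > length(masks) / 2) * 1
}

#' Aggregate per-image metrics into a report
#'
#' Computes mean and standard error of the mean (sample sd over
#' `sqrt(n)`) of each metric per strategy, mirroring a results table of
#' per-image evaluations.
#'
#' @param per_image data frame with columns `strategy`, `image_id`, and
#'   the metric columns `DSC`, `precision`, `sensitivity`,
#'   `specificity`.
#' @return a `metrics_report`: list with the `per_image` rows and an
#'   `aggregate` data frame (one row per strategy/metric with `mean` and
#'   `sem`).
#' @export
aggregate_report <- function(per_image) {
  metric_cols <- intersect(c("DSC", "precision", "sensitivity",
                             "specificity"), names(per_image))
  if (!length(metric_cols)) stop("no metric columns found")
  agg <- do.call(rbind, lapply(split(per_image, per_image$strategy),
    function(df) {
      do.call(rbind, lapply(metric_cols, function(mc) {
        x <- df[[mc]]
        n <- length(x)
        data.frame(strategy = df$strategy[1], metric = mc,
                   mean = mean(x),
                   sem = if (n > 1) stats::sd(x) / sqrt(n) else NaN,
                   n = n)
      }))
    }))
  rownames(agg) <- NULL
  structure(list(per_image = per_image, aggregate = agg),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics (mean ± SEM, %)\n")
  wide <- stats::reshape(
    transform(x$aggregate,
              cell = sprintf("%.2f ± %.2f", 100 * mean, 100 * sem))[,
                c("strategy", "metric", "cell")],
    idvar = "strategy", timevar = "metric", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' One row per (strategy, image) with metrics as percentages to two
#' decimals, followed by aggregate mean/SEM rows.
#'
#' @param report a `metrics_report`.
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(report, path) {
  per <- report$per_image
  for (mc in c("DSC", "precision", "sensitivity", "specificity"))
    if (mc %in% names(per)) per[[mc]] <- round(100 * per[[mc]], 2)
  utils::write.csv(per, path, row.names = FALSE)
  agg <- report$aggregate
  agg$mean <- round(100 * agg$mean, 2); agg$sem <- round(100 * agg$sem, 2)
  agg_path <- sub("(\\.csv)?$", "_aggregate.csv", path)
  utils::write.csv(agg, agg_path, row.names = FALSE)
  invisible(c(path, agg_path))
}
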