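# Independent brute-force oracles and small fixture builders shared by
# the tests. Oracles deliberately use direct enumeration, not the
# package's vectorized/histogram code paths.

# Binary dilation as the literal union of mask translates by each active
# kernel offset, translates clipped to the frame.
oracle_dilate <- function(mask, kernel_support) {
  n <- nrow(mask); m <- ncol(mask)
  anchor <- (dim(kernel_support) + 1) %/% 2
  out <- matrix(0, n, m)
  for (u in seq_len(nrow(kernel_support)))
    for (v in seq_len(ncol(kernel_support))) {
      if (kernel_support[u, v] == 0) next
      dr <- u - anchor[1]; dc <- v - anchor[2]
      src_r <- seq_len(n) - dr; src_c <- seq_len(m) - dc
      ok_r <- src_r >= 1 & src_r <= n; ok_c <- src_c >= 1 & src_c <= m
      out[ok_r, ok_c] <- pmax(out[ok_r, ok_c],
                              mask[src_r[ok_r], src_c[ok_c]])
    }
  out
}

# Otsu by exhaustive scan: for every candidate cut, split pixels by bin
# membership and compute the between-class variance from the raw values.
oracle_otsu <- function(img, n_bins = 256L) {
  x <- as.numeric(img)
  bin <- pmin(floor(x * n_bins), n_bins - 1L)
  best <- -Inf; best_t <- NA_real_
  for (t in seq_len(n_bins - 1L)) {
    lo <- bin < t
    n0 <- sum(lo); n1 <- length(x) - n0
    if (n0 == 0L || n1 == 0L) next
    w0 <- n0 / length(x); w1 <- 1 - w0
    # class means on the histogram's bin-centre scale, matching the
    # discretization any histogram method sees
    mu0 <- mean((bin[lo] + 0.5) / n_bins)
    mu1 <- mean((bin[!lo] + 0.5) / n_bins)
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-15) { best <- v; best_t <- t / n_bins }
  }
  best_t
}

rand_mask <- function(n, m = n, p = 0.3) matrix(stats::rbinom(n * m, 1, p), n, m)

rand_image <- function(n, m = n) {
  # 8-bit style image on the bin-centre grid
  matrix((sample.int(256, n * m, replace = TRUE) - 0.5) / 256, n, m)
}

# shared desk-scale fixture pair, built once per test run
tiny_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_domain_pair(12, 12, size = 64, seed = 7)
    cache
  }
})
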