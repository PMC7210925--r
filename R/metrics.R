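#' Immerkaer fast noise estimate
#'
#' Estimates the standard deviation of additive zero-mean Gaussian noise
#' from a single image by convolving the interior with the 3 x 3
#' second-difference mask `[[1,-2,1],[-2,4,-2],[1,-2,1]]` and averaging the
#' absolute response:
#' \deqn{\hat\sigma = \sqrt{\pi/2}\,\frac{1}{6 (W-2)(H-2)} \sum |I * M|.}
#' The mask annihilates constant and planar images exactly, so structure
#' with locally linear shading contributes nothing.
#'
#' @param img A [bscan()] or numeric matrix, at least 3 x 3.
#' @return Nonnegative noise sigma estimate (intensity units).
#' @export
immerkaer_noise <- function(img) {
  m <- as.matrix(img)
  H <- nrow(m); W <- ncol(m)
  if (H < 3 || W < 3) stop_invalid("image must be at least 3 x 3")
  i <- 2:(H - 1); j <- 2:(W - 1)
  resp <- 4 * m[i, j] -
    2 * (m[i - 1, j] + m[i + 1, j] + m[i, j - 1] + m[i, j + 1]) +
    (m[i - 1, j - 1] + m[i - 1, j + 1] + m[i + 1, j - 1] + m[i + 1, j + 1])
  sqrt(pi / 2) * sum(abs(resp)) / (6 * (W - 2) * (H - 2))
}

#' Rectangular window pair for SNR
#'
#' Windows are half-open, 0-based row/column intervals `[from, to)`, must
#' lie inside the image they are applied to, contain at least 16 pixels
#' each, and be disjoint.
#'
#' @param signal_rows,signal_cols Integer vectors `c(from, to)` for the
#'   signal window.
#' @param noise_rows,noise_cols Likewise for the noise window.
#' @return A `window_pair` object.
#' @export
window_pair <- function(signal_rows, signal_cols, noise_rows, noise_cols) {
  chk <- function(iv, what) {
    if (length(iv) != 2 || iv[2] <= iv[1] || iv[1] < 0) {
      stop_invalid("invalid %s interval", what)
    }
    as.integer(iv)
  }
  wp <- structure(list(
    signal_rows = chk(signal_rows, "signal row"),
    signal_cols = chk(signal_cols, "signal col"),
    noise_rows = chk(noise_rows, "noise row"),
    noise_cols = chk(noise_cols, "noise col")
  ), class = "window_pair")
  npix <- function(r, c) (r[2] - r[1]) * (c[2] - c[1])
  if (npix(wp$signal_rows, wp$signal_cols) < 16 ||
      npix(wp$noise_rows, wp$noise_cols) < 16) {
    stop_invalid("each window must contain at least 16 pixels")
  }
  overlap <- function(a, b) max(a[1], b[1]) < min(a[2], b[2])
  if (overlap(wp$signal_rows, wp$noise_rows) &&
      overlap(wp$signal_cols, wp$noise_cols)) {
    stop_invalid("signal and noise windows must be disjoint")
  }
  wp
}

extract_window <- function(m, rows, cols) {
  if (rows[2] > nrow(m) || cols[2] > ncol(m)) {
    stop_invalid("window exceeds image bounds")
  }
  m[(rows[1] + 1):rows[2], (cols[1] + 1):cols[2]]
}

#' Window-based signal-to-noise ratio
#'
#' The study design lacks a pure-background region for classical SNR, so a
#' window in a noisy (structure-free) area is compared against a window with
#' signal: `SNR = mean(signal window) / sd(noise window)`. The ratio is
#' invariant under global positive rescaling of the image and grows as
#' `sqrt(N)` under N-frame averaging of uncorrelated noise.
#'
#' @param img A [bscan()] or matrix.
#' @param windows A [window_pair()].
#' @return SNR (unitless ratio).
#' @export
window_snr <- function(img, windows) {
  m <- as.matrix(img)
  s <- extract_window(m, windows$signal_rows, windows$signal_cols)
  n <- extract_window(m, windows$noise_rows, windows$noise_cols)
  sn <- sd(as.vector(n))
  if (sn == 0) stop_invalid("noise window has zero variance (degenerate)")
  mean(s) / sn
}

#' Default SNR windows for a phantom
#'
#' Noise window: the structure-free vitreous strip at the top of the image.
#' Signal window: the rows spanned by the bright (RPE-like) band, from its
#' boundary curves. Both use the central 80% of columns.
#'
#' @param truth A `phantom_truth`.
#' @return A [window_pair()].
#' @export
default_windows <- function(truth) {
  H <- nrow(truth$clean); W <- ncol(truth$clean)
  cols <- c(floor(0.1 * W), ceiling(0.9 * W))
  bl <- truth$config$bright_layer
  top <- floor(min(truth$boundaries[bl, ]))
  bot <- ceiling(max(truth$boundaries[bl + 1L, ]))
  sig_rows <- c(max(top, 0), min(bot, H))
  noise_rows <- c(0, max(floor(min(truth$boundaries[1, ])) - 2L, 4L))
  window_pair(sig_rows, cols, noise_rows, cols)
}

gaussian_kernel_1d <- function(size, sigma) {
  half <- (size - 1) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# Banded matrix applying a 1-D valid correlation along rows: (n-size+1) x n.
valid_band_matrix <- function(n, k) {
  size <- length(k)
  m <- matrix(0, n - size + 1, n)
  for (i in seq_len(n - size + 1)) m[i, i:(i + size - 1)] <- k
  m
}

ssim_components <- function(a, b, window, sigma, K1, K2, L) {
  H <- nrow(a); W <- ncol(a)
  win <- min(window, H, W)
  if (win %% 2 == 0) win <- win - 1L
  k <- gaussian_kernel_1d(win, sigma)
  KH <- valid_band_matrix(H, k)
  KW <- valid_band_matrix(W, k)
  filt <- function(x) KH %*% x %*% t(KW)
  mu_a <- filt(a); mu_b <- filt(b)
  m2a <- filt(a * a); m2b <- filt(b * b); mab <- filt(a * b)
  va <- m2a - mu_a^2; vb <- m2b - mu_b^2; cab <- mab - mu_a * mu_b
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  A1 <- 2 * mu_a * mu_b + C1; A2 <- 2 * cab + C2
  B1 <- mu_a^2 + mu_b^2 + C1; B2 <- va + vb + C2
  S <- (A1 * A2) / (B1 * B2)
  list(S = S, mu_a = mu_a, mu_b = mu_b, A1 = A1, A2 = A2, B1 = B1, B2 = B2,
       KH = KH, KW = KW)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sigma 1.5), stability
#' constants `K1 = 0.01`, `K2 = 0.03`, dynamic range 1. Local statistics use
#' valid (interior-only) filtering, so the map excludes a `(window-1)/2`
#' border. For images smaller than the window, the window shrinks to the
#' largest odd size that fits (kernel renormalized).
#'
#' @param a,b Images of identical dimensions (matrices or [bscan()]).
#' @param window Odd window size (default 11).
#' @param sigma Gaussian window standard deviation in pixels (default 1.5).
#' @param K1,K2 Stability constants.
#' @param L Dynamic range of the data (1 for `[0, 1]` images).
#' @return Similarity in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 L = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop_invalid("SSIM: dimension mismatch")
  mean(ssim_components(a, b, window, sigma, K1, K2, L)$S)
}

# SSIM value plus analytic gradient with respect to `a`; used by the
# training loss. Derivation: S = (A1 A2)/(B1 B2) with A1 = 2 mu_a mu_b + C1,
# A2 = 2 cov + C2, B1 = mu_a^2 + mu_b^2 + C1, B2 = var_a + var_b + C2, where
# mu_a = G*a, var_a = G*a^2 - mu_a^2, cov = G*(ab) - mu_a mu_b. Treating
# (mu_a, G*a^2, G*ab) as the filtered quantities and pushing the adjoint of
# the (separable, valid) Gaussian filter through each term gives
#   d mean(S)/da = [ adj(dS/dmu_a) + 2 a adj(-S/B2) + b adj(2S/A2) ] / |S|
# with dS/dmu_a = 2 mu_b S (1/A1 - 1/A2) - 2 mu_a S (1/B1 - 1/B2).
ssim_with_grad <- function(a, b, window = 11L, sigma = 1.5, K1 = 0.01,
                           K2 = 0.03, L = 1) {
  cs <- ssim_components(a, b, window, sigma, K1, K2, L)
  S <- cs$S
  ns <- length(S)
  adj <- function(g) t(cs$KH) %*% g %*% cs$KW
  d_mu <- 2 * cs$mu_b * S * (1 / cs$A1 - 1 / cs$A2) -
    2 * cs$mu_a * S * (1 / cs$B1 - 1 / cs$B2)
  grad <- (adj(d_mu) + 2 * a * adj(-S / cs$B2) + b * adj(2 * S / cs$A2)) / ns
  list(value = mean(S), grad = grad)
}

#' Mean absolute error between two images
#'
#' @param a,b Images of identical dimensions.
#' @return Mean absolute pixel difference (nonnegative).
#' @export
mae <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop_invalid("MAE: dimension mismatch")
  mean(abs(a - b))
}

#' Paired pre/post comparison of quality measures
#'
#' Paired Student's t-test on per-image quality values before and after
#' enhancement (two-sided), the test used for the objective metrics.
#'
#' @param before,after Equal-length numeric vectors (n >= 3), paired by
#'   image.
#' @return A tibble with `statistic`, `p_value`, `df`, `mean_difference`,
#'   `n`.
#' @export
paired_quality_stats <- function(before, after) {
  if (length(before) != length(after)) stop_invalid("length mismatch")
  if (length(before) < 3) stop_invalid("need at least 3 pairs")
  d <- after - before
  if (sd(d) == 0) {
    stop_invalid("all paired differences identical: zero variance (degenerate)")
  }
  ht <- stats::t.test(after, before, paired = TRUE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    df = unname(ht$parameter),
    mean_difference = mean(d),
    n = length(d)
  )
}

#' Per-image quality report for original vs enhanced image sets
#'
#' Computes the objective evaluation battery on paired image lists: the
#' Immerkaer noise estimate and window SNR per image and condition, SSIM and
#' MAE to a clean reference when one is available, plus paired t-tests
#' across the set for each metric.
#'
#' @param original,enhanced Lists of [bscan()]s, paired by position.
#' @param clean Optional list of clean references.
#' @param windows A [window_pair()] or list of them (one per image); if
#'   `NULL`, SNR is skipped.
#' @return A `quality_report`: list with `per_image` (tibble, one row per
#'   image and condition) and `tests` (tibble of paired statistics).
#' @export
quality_report <- function(original, enhanced, clean = NULL, windows = NULL) {
  if (length(original) != length(enhanced)) stop_invalid("length mismatch")
  n <- length(original)
  win_i <- function(i) {
    if (is.null(windows)) NULL
    else if (inherits(windows, "window_pair")) windows
    else windows[[i]]
  }
  row_for <- function(img, i, condition) {
    w <- win_i(i)
    tibble::tibble(
      image = i, condition = condition,
      noise_estimate = immerkaer_noise(img),
      snr = if (is.null(w)) NA_real_ else window_snr(img, w),
      ssim_to_reference = if (is.null(clean)) NA_real_ else ssim(img, clean[[i]]),
      mae_to_reference = if (is.null(clean)) NA_real_ else mae(img, clean[[i]])
    )
  }
  per_image <- dplyr::bind_rows(
    purrr::map2(original, seq_len(n), row_for, condition = "original"),
    purrr::map2(enhanced, seq_len(n), row_for, condition = "enhanced")
  )
  test_for <- function(metric) {
    x <- dplyr::filter(per_image, .data$condition == "original")[[metric]]
    y <- dplyr::filter(per_image, .data$condition == "enhanced")[[metric]]
    if (anyNA(x) || anyNA(y) || sd(y - x) == 0) return(NULL)
    dplyr::mutate(paired_quality_stats(x, y), metric = metric, .before = 1)
  }
  tests <- dplyr::bind_rows(purrr::compact(purrr::map(
    c("noise_estimate", "snr", "ssim_to_reference", "mae_to_reference"),
    test_for
  )))
  structure(list(per_image = per_image, tests = tests),
            class = "quality_report")
}

#' @exportS3Method generics::tidy
tidy.quality_report <- function(x, ...) x$per_image

#' @exportS3Method generics::glance
glance.quality_report <- function(x, ...) x$tests
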