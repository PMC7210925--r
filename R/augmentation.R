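#' Augmentation pipeline configuration
#'
#' The stochastic corruption pipeline applied to network inputs during
#' training. Each of the four corruption groups (noise, intensity,
#' geometric, blur) activates independently with probability `p_apply`;
#' active groups draw their parameters uniformly from the configured
#' intervals, refreshed once per training mini-batch. Defaults follow the
#' training recipe: intensity manipulation `a * x^g + b` with a, b, g in
#' `[0.5, 1.5]`; rotation in `[-45, 45]` degrees; scale in `[50%, 150%]`;
#' Gaussian blur with standard deviation 1.0; 50% activation probability.
#'
#' Note `b` drawn from `[0.5, 1.5]` saturates heavily after clipping to
#' `[0, 1]`; the interval follows the published recipe literally and is
#' overridable here.
#'
#' @param a_range,b_range,g_range Intervals for the intensity transform
#'   parameters.
#' @param r_range Rotation interval in degrees.
#' @param s_range Scale interval (fractions; 1 = unchanged).
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param noise A [noise_spec()] used by the noise group.
#' @param p_apply Per-group activation probability in `[0, 1]`.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(a_range = c(0.5, 1.5), b_range = c(0.5, 1.5),
                                g_range = c(0.5, 1.5), r_range = c(-45, 45),
                                s_range = c(0.5, 1.5), blur_sigma = 1.0,
                                noise = noise_spec("gaussian", sigma = 0.5),
                                p_apply = 0.5) {
  for (iv in list(a_range, b_range, g_range, r_range, s_range)) {
    if (length(iv) != 2 || iv[1] > iv[2]) stop_invalid("interval reversed")
  }
  if (p_apply < 0 || p_apply > 1) stop_invalid("p_apply must lie in [0, 1]")
  if (blur_sigma < 0) stop_invalid("blur_sigma must be >= 0")
  structure(list(a_range = a_range, b_range = b_range, g_range = g_range,
                 r_range = r_range, s_range = s_range,
                 blur_sigma = blur_sigma, noise = noise, p_apply = p_apply),
            class = "augmentation_config")
}

#' Brightness / contrast / gamma manipulation
#'
#' Applies `clip(a * img^g + b, 0, 1)` pixel-wise.
#'
#' @param img A [bscan()] or matrix in `[0, 1]`.
#' @param a,b,g Contrast, brightness and gamma parameters; `g` must be
#'   positive.
#' @return Transformed image, same dimensions.
#' @export
intensity_transform <- function(img, a = 1, b = 0, g = 1) {
  if (g <= 0) stop_invalid("gamma must be > 0")
  img <- as_bscan(img)
  if (a == 1 && b == 0 && g == 1) return(img)
  rewrap_bscan(clamp01(a * unclass(img)^g + b), img)
}

# Mirror a continuous coordinate into [1, n] (symmetric reflection about
# the pixel centers at the edges).
reflect_coord <- function(v, n) {
  if (n == 1) return(rep(1, length(v)))
  period <- 2 * (n - 1)
  v <- (v - 1) %% period
  ifelse(v > (n - 1), period - v, v) + 1
}

bilinear_sample <- function(m, rows, cols) {
  H <- nrow(m); W <- ncol(m)
  rows <- reflect_coord(rows, H)
  cols <- reflect_coord(cols, W)
  r0 <- pmin(floor(rows), H - 1); c0 <- pmin(floor(cols), W - 1)
  fr <- rows - r0; fc <- cols - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Rotation and scaling about the image center
#'
#' Rotates by `r` degrees and rescales by `s` about the center, resampling
#' bilinearly onto the original grid with reflect padding; output
#' dimensions are unchanged. `r = 0`, `s = 1` short-circuits to the exact
#' input.
#'
#' @param img A [bscan()] or matrix.
#' @param r Rotation in degrees (counter-clockwise).
#' @param s Scale fraction (> 0; 1 = unchanged, 0.5 = half size).
#' @return Transformed image, same dimensions.
#' @export
geometric_transform <- function(img, r = 0, s = 1) {
  if (s <= 0) stop_invalid("scale must be > 0")
  img <- as_bscan(img)
  if (r == 0 && s == 1) return(img)
  m <- unclass(img)
  H <- nrow(m); W <- ncol(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  theta <- r * pi / 180
  grid <- expand.grid(row = seq_len(H), col = seq_len(W))
  dy <- (grid$row - cy) / s; dx <- (grid$col - cx) / s
  # Inverse map of "rotate then scale about the center".
  src_r <- cos(theta) * dy - sin(theta) * dx + cy
  src_c <- sin(theta) * dy + cos(theta) * dx + cx
  out <- matrix(bilinear_sample(m, src_r, src_c), H, W)
  rewrap_bscan(clamp01(out), img)
}

#' Isotropic Gaussian blur with reflect boundary
#'
#' Separable Gaussian convolution, kernel truncated at four standard
#' deviations and renormalized; `sigma = 0` is the identity. Constant
#' images are unchanged and the image mean is preserved up to boundary
#' effects.
#'
#' @param img A [bscan()] or matrix.
#' @param sigma Blur standard deviation in pixels (>= 0).
#' @return Blurred image, same dimensions.
#' @export
gaussian_blur <- function(img, sigma = 1.0) {
  if (sigma < 0) stop_invalid("sigma must be >= 0")
  img <- as_bscan(img)
  if (sigma == 0) return(img)
  m <- unclass(img)
  H <- nrow(m); W <- ncol(m)
  radius <- max(1L, ceiling(4 * sigma))
  k <- gaussian_kernel_1d(2L * radius + 1L, sigma)
  ridx <- reflect_coord(c((1 - radius):0, seq_len(H), H + seq_len(radius)), H)
  cidx <- reflect_coord(c((1 - radius):0, seq_len(W), W + seq_len(radius)), W)
  padded <- m[ridx, cidx]
  out <- valid_band_matrix(H + 2L * radius, k) %*% padded %*%
    t(valid_band_matrix(W + 2L * radius, k))
  rewrap_bscan(clamp01(out), img)
}

#' Draw one composed augmentation
#'
#' Independently activates each of the four corruption groups (noise,
#' intensity, geometric, blur) with probability `p_apply` and draws the
#' parameters of active groups uniformly from their intervals. Returns the
#' drawn parameter record together with apply functions; replaying the same
#' record reproduces outputs bit-identically. Composition order is fixed:
#' noise, then intensity, then geometric, then blur.
#'
#' During supervised training the geometric group must hit input and target
#' identically (they must stay registered), while noise, intensity and blur
#' corrupt the input only; `apply_target()` therefore replays only the
#' geometric part of the draw.
#'
#' @param config An [augmentation_config()].
#' @param rng_state Integer seed for the draw.
#' @return An `augmentation_draw` list with `params` (named list) and
#'   functions `apply_input(img)`, `apply_target(img)`.
#' @export
sample_augmentation <- function(config = augmentation_config(),
                                rng_state = 1L) {
  if (!inherits(config, "augmentation_config")) {
    stop_invalid("`config` must be an augmentation_config")
  }
  params <- with_local_seed(rng_state, {
    active <- runif(4) < config$p_apply
    list(
      noise = active[1], intensity = active[2], geometric = active[3],
      blur = active[4],
      noise_seed = sample.int(2147483646L, 1),
      a = runif(1, config$a_range[1], config$a_range[2]),
      b = runif(1, config$b_range[1], config$b_range[2]),
      g = runif(1, config$g_range[1], config$g_range[2]),
      r = runif(1, config$r_range[1], config$r_range[2]),
      s = runif(1, config$s_range[1], config$s_range[2]),
      blur_sigma = config$blur_sigma
    )
  })
  structure(list(
    params = params,
    apply_input = function(img) augment_apply(img, params, config, "input"),
    apply_target = function(img) augment_apply(img, params, config, "target")
  ), class = "augmentation_draw")
}

# Replay a recorded augmentation draw on an image. role = "target" applies
# only the geometric component (keeps input/target registered).
augment_apply <- function(img, params, config, role = c("input", "target")) {
  role <- match.arg(role)
  img <- as_bscan(img)
  if (role == "input") {
    if (params$noise) img <- add_noise(img, config$noise, params$noise_seed)
    if (params$intensity) {
      img <- intensity_transform(img, params$a, params$b, params$g)
    }
  }
  if (params$geometric) img <- geometric_transform(img, params$r, params$s)
  if (role == "input" && params$blur) {
    img <- gaussian_blur(img, params$blur_sigma)
  }
  img
}
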