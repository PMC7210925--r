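#' Phantom generation parameters
#'
#' Controls the synthetic layered-retina B-scan generator. Phantoms consist
#' of smooth horizontal tissue bands (one bright, RPE-like), optional dark
#' vessel shadows cast downward, and an exponentially attenuating
#' choroid-like region below the deepest boundary. They stand in for retinal
#' anatomy in supervised denoising experiments; they are not a physical
#' model of OCT image formation.
#'
#' @param height,width Image size in pixels (each at least 8).
#' @param n_layers Number of retinal bands (at least 2; default 6).
#' @param background Intensity of the vitreous region above the retina.
#' @param refl_range Interval from which per-layer mean reflectivities are
#'   drawn.
#' @param bright_layer Index of the bright (RPE-like) band; default the
#'   second-deepest band.
#' @param bright_value Reflectivity of the bright band.
#' @param n_vessels Number of vessel shadows (0 or more).
#' @param vessel_strength Maximal fractional darkening under a vessel.
#' @param attenuation_rate Per-row exponential decay constant of the
#'   choroid-like signal below the deepest boundary.
#' @param choroid_value Choroid intensity immediately below the deepest
#'   boundary, before attenuation.
#' @param edge_softness Width (pixels) of the sigmoid transition at layer
#'   boundaries.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(height = 64, width = 64, n_layers = 6,
                           background = 0.15, refl_range = c(0.25, 0.6),
                           bright_layer = NULL, bright_value = 0.9,
                           n_vessels = 2, vessel_strength = 0.6,
                           attenuation_rate = 0.05, choroid_value = 0.55,
                           edge_softness = 0.75) {
  if (height < 8 || width < 8) {
    stop_invalid("phantom dimensions must be at least 8 x 8")
  }
  if (n_layers < 2) stop_invalid("phantom needs at least 2 layers")
  if (n_vessels < 0) stop_invalid("vessel count must be >= 0")
  if (refl_range[1] > refl_range[2]) stop_invalid("refl_range reversed")
  if (is.null(bright_layer)) bright_layer <- max(n_layers - 1L, 1L)
  structure(list(
    height = as.integer(height), width = as.integer(width),
    n_layers = as.integer(n_layers), background = background,
    refl_range = refl_range, bright_layer = as.integer(bright_layer),
    bright_value = bright_value, n_vessels = as.integer(n_vessels),
    vessel_strength = vessel_strength, attenuation_rate = attenuation_rate,
    choroid_value = choroid_value, edge_softness = edge_softness
  ), class = "phantom_config")
}

# Smooth zero-mean lateral profile: a few random low-frequency cosines.
smooth_profile <- function(width) {
  x <- seq_len(width) / width
  p <- numeric(width)
  for (k in 1:3) {
    p <- p + runif(1, -1, 1) * cos(2 * pi * (k * runif(1, 0.3, 1)) * x +
                                     runif(1, 0, 2 * pi))
  }
  p / 3
}

#' Generate a clean layered-retina phantom
#'
#' Deterministic for a fixed `(config, seed)` pair. The returned object
#' carries the clean image together with the generating geometry: the
#' `n_layers + 1` non-crossing boundary curves (row index as a function of
#' column), per-layer reflectivities, vessel positions and the choroidal
#' attenuation rate, so that tests can re-render the image independently.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed.
#' @return A `phantom_truth` list with fields `clean` ([bscan()]),
#'   `boundaries` (matrix `(n_layers + 1) x width`), `layer_reflectivities`,
#'   `vessel_columns` (tibble with `center`, `width`), `attenuation_rate`.
#' @export
generate_clean_bscan <- function(config = phantom_config(), seed = 1L) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  H <- config$height; W <- config$width; nl <- config$n_layers
  with_local_seed(seed, {
    cols <- seq_len(W)
    top <- H * runif(1, 0.28, 0.38) + H * 0.05 * smooth_profile(W)
    total <- H * runif(1, 0.3, 0.42)
    frac <- runif(nl, 0.5, 1.5)
    frac <- frac / sum(frac)
    boundaries <- matrix(0, nl + 1L, W)
    boundaries[1, ] <- top
    for (k in seq_len(nl)) {
      boundaries[k + 1L, ] <- boundaries[k, ] + total * frac[k]
    }
    refl <- runif(nl, config$refl_range[1], config$refl_range[2])
    refl[config$bright_layer] <- config$bright_value

    w <- config$edge_softness
    rows <- seq_len(H)
    # s[[k]](r, x): soft indicator of "row r below boundary k".
    img <- matrix(0, H, W)
    s_prev <- stats::plogis(outer(rows, boundaries[1, ], function(r, b) (r - b) / w))
    img <- img + config$background * (1 - s_prev)
    for (k in seq_len(nl)) {
      s_k <- stats::plogis(outer(rows, boundaries[k + 1L, ], function(r, b) (r - b) / w))
      img <- img + refl[k] * (s_prev - s_k)
      if (k == 2L) s_shadow_from <- s_k
      s_prev <- s_k
    }
    if (nl < 2L) s_shadow_from <- s_prev
    depth_below <- outer(rows, boundaries[nl + 1L, ], function(r, b) pmax(r - b, 0))
    img <- img + config$choroid_value *
      exp(-config$attenuation_rate * depth_below) * s_prev

    vessels <- tibble::tibble(center = numeric(0), width = numeric(0))
    if (config$n_vessels > 0) {
      centers <- runif(config$n_vessels, 0.15 * W, 0.85 * W)
      widths <- runif(config$n_vessels, 1.5, 4)
      vessels <- tibble::tibble(center = centers, width = widths)
      for (v in seq_len(config$n_vessels)) {
        profile <- exp(-(cols - centers[v])^2 / (2 * widths[v]^2))
        # Shadow darkens everything below the inner retinal layers.
        shade <- 1 - config$vessel_strength *
          matrix(profile, H, W, byrow = TRUE) * s_shadow_from
        img <- img * shade
      }
    }

    clean <- bscan(clamp01(img), meta = list(kind = "phantom", seed = seed))
    structure(list(
      clean = clean, boundaries = boundaries, layer_reflectivities = refl,
      vessel_columns = vessels, attenuation_rate = config$attenuation_rate,
      config = config, seed = seed
    ), class = "phantom_truth")
  })
}

#' Noise model specification
#'
#' Additive noise models for simulated OCT acquisition and for training
#' augmentation. Defaults follow the two augmentation corruptions used for
#' network training: Gaussian with standard deviation 0.5 and Rayleigh with
#' sigma 0.2. Rayleigh noise is mean-uncentered (its support is
#' nonnegative). A multiplicative (speckle-style) variant is available
#' behind `multiplicative = TRUE` but off by default.
#'
#' @param model `"gaussian"` or `"rayleigh"`.
#' @param sigma Noise scale (intensity units); defaults 0.5 for Gaussian,
#'   0.2 for Rayleigh.
#' @param correlation Fraction in `[0, 1]` of noise variance shared across
#'   repeated frames of the same scan.
#' @param jitter_px Fixation-jitter amplitude: frames are laterally shifted
#'   by a uniform integer in `[-jitter_px, jitter_px]` before averaging.
#' @param multiplicative If `TRUE`, noise multiplies (`img * (1 + n)`)
#'   instead of adding.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(model = c("gaussian", "rayleigh"), sigma = NULL,
                       correlation = 0, jitter_px = 0,
                       multiplicative = FALSE) {
  if (length(model) == 1 && !model %in% c("gaussian", "rayleigh")) {
    stop_invalid("unknown noise model '%s'", model)
  }
  model <- match.arg(model)
  if (is.null(sigma)) sigma <- if (model == "gaussian") 0.5 else 0.2
  if (sigma < 0) stop_invalid("sigma must be >= 0")
  if (correlation < 0 || correlation > 1) {
    stop_invalid("correlation must lie in [0, 1]")
  }
  if (jitter_px < 0) stop_invalid("jitter_px must be >= 0")
  structure(list(model = model, sigma = sigma, correlation = correlation,
                 jitter_px = jitter_px, multiplicative = multiplicative),
            class = "noise_spec")
}

draw_noise_field <- function(n, spec) {
  if (spec$sigma == 0) return(numeric(n))
  switch(spec$model,
    gaussian = rnorm(n, 0, spec$sigma),
    rayleigh = spec$sigma * sqrt(-2 * log(runif(n))),
    stop_invalid("unknown noise model '%s'", spec$model)
  )
}

#' Corrupt a B-scan with additive noise
#'
#' Draws an i.i.d. per-pixel noise field from the model named in `spec` and
#' adds it to the image (or multiplies, for the speckle-style variant), then
#' clips to `[0, 1]`. Deterministic per seed.
#'
#' @param img A [bscan()].
#' @param spec A [noise_spec()].
#' @param seed Integer seed.
#' @return Corrupted [bscan()] with the same dimensions.
#' @export
add_noise <- function(img, spec = noise_spec(), seed = 1L) {
  img <- as_bscan(img)
  if (!inherits(spec, "noise_spec")) stop_invalid("`spec` must be a noise_spec")
  if (spec$sigma == 0) return(img)
  with_local_seed(seed, {
    field <- matrix(draw_noise_field(length(img), spec), nrow(img), ncol(img))
    out <- if (spec$multiplicative) unclass(img) * (1 + field) else unclass(img) + field
    rewrap_bscan(clamp01(out), img)
  })
}

# Lateral integer shift with edge replication.
shift_lateral <- function(m, s) {
  if (s == 0) return(m)
  idx <- pmin(pmax(seq_len(ncol(m)) - s, 1L), ncol(m))
  m[, idx, drop = FALSE]
}

#' Simulate an N-frame averaged acquisition
#'
#' Draws `n_frames` corrupted frames of the phantom. A shared noise
#' component (weight `spec$correlation`) models frame-to-frame correlated
#' noise; each frame is laterally shifted by a random integer within
#' `c(-1, 1) * spec$jitter_px` (fixation jitter) before averaging. Returns the
#' first frame as `noisy`, the frame mean as `averaged`, and the phantom's
#' clean image as `clean`.
#'
#' @param truth A `phantom_truth` from [generate_clean_bscan()].
#' @param n_frames Number of frames N (>= 1); the study acquisition uses 9.
#' @param spec A [noise_spec()].
#' @param seed Integer seed.
#' @return A `paired_sample` list with `noisy`, `averaged`, `clean`,
#'   `n_frames`.
#' @export
simulate_averaged_scan <- function(truth, n_frames = 9L,
                                   spec = noise_spec("gaussian", sigma = 0.1),
                                   seed = 1L) {
  if (n_frames < 1) stop_invalid("n_frames must be >= 1")
  clean <- unclass(truth$clean)
  H <- nrow(clean); W <- ncol(clean)
  with_local_seed(seed, {
    rho <- spec$correlation
    shared <- matrix(draw_noise_field(H * W, spec), H, W)
    acc <- matrix(0, H, W)
    noisy <- NULL
    for (i in seq_len(n_frames)) {
      eps <- matrix(draw_noise_field(H * W, spec), H, W)
      field <- sqrt(rho) * shared + sqrt(1 - rho) * eps
      s <- if (spec$jitter_px > 0) {
        sample.int(2L * as.integer(spec$jitter_px) + 1L, 1L) -
          as.integer(spec$jitter_px) - 1L
      } else 0L
      base <- shift_lateral(clean, s)
      frame <- if (spec$multiplicative) base * (1 + field) else base + field
      frame <- clamp01(frame)
      if (i == 1L) noisy <- frame
      acc <- acc + frame
    }
    structure(list(
      noisy = rewrap_bscan(noisy, truth$clean, list(role = "noisy")),
      averaged = rewrap_bscan(acc / n_frames, truth$clean, list(role = "averaged")),
      clean = truth$clean,
      n_frames = as.integer(n_frames)
    ), class = "paired_sample")
  })
}

#' Build a paired phantom dataset with a train/test split
#'
#' Generates `n_samples` independent phantoms, simulates an N-frame averaged
#' acquisition for each, and splits the samples into train and test
#' partitions that are disjoint by phantom (no frame of a test phantom is
#' ever seen in training). Deterministic per seed.
#'
#' @param n_samples Number of samples (>= 2).
#' @param config A [phantom_config()].
#' @param seed Integer seed.
#' @param split Train fraction in (0, 1).
#' @param n_frames Frames averaged per sample (default 9, the study
#'   acquisition protocol).
#' @param noise A [noise_spec()]; default additive Gaussian sigma 0.1, the
#'   package's standing acquisition-noise condition for phantoms.
#' @return A `paired_dataset` list with `train`, `test` (lists of
#'   `paired_sample`) and a `manifest` tibble.
#' @export
make_paired_dataset <- function(n_samples, config = phantom_config(),
                                seed = 1L, split = 0.8, n_frames = 9L,
                                noise = noise_spec("gaussian", sigma = 0.1)) {
  if (n_samples < 2) stop_invalid("n_samples must be >= 2")
  if (split <= 0 || split >= 1) stop_invalid("split must lie in (0, 1)")
  with_local_seed(seed, {
    phantom_seeds <- sample.int(2147483646L, n_samples)
    noise_seeds <- sample.int(2147483646L, n_samples)
    samples <- purrr::map(seq_len(n_samples), function(i) {
      truth <- generate_clean_bscan(config, phantom_seeds[i])
      s <- simulate_averaged_scan(truth, n_frames, noise, noise_seeds[i])
      s$truth <- truth
      s$id <- sprintf("phantom_%04d", i)
      s
    })
    n_train <- floor(split * n_samples)
    manifest <- tibble::tibble(
      id = purrr::map_chr(samples, "id"),
      phantom_seed = phantom_seeds,
      noise_seed = noise_seeds,
      n_frames = as.integer(n_frames),
      model = noise$model,
      sigma = noise$sigma,
      partition = c(rep("train", n_train), rep("test", n_samples - n_train))
    )
    structure(list(
      train = samples[seq_len(n_train)],
      test = samples[setdiff(seq_len(n_samples), seq_len(n_train))],
      manifest = manifest, config = config, noise = noise, seed = seed
    ), class = "paired_dataset")
  })
}
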