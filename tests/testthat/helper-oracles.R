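# Independent brute-force oracles and small fixtures shared across tests.
# Oracles are deliberately naive (loops, direct formulas) and never call the
# package's own implementation paths.

tiny_phantom_config <- function(...) {
  args <- list(height = 32, width = 32, n_layers = 4, n_vessels = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}

rand_img <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# Sliding-window SSIM computed directly per window position (valid region),
# Gaussian-weighted statistics written out longhand.
oracle_ssim <- function(a, b, win = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  H <- nrow(a); W <- ncol(a)
  win <- min(win, H, W)
  if (win %% 2 == 0) win <- win - 1L
  half <- (win - 1L) / 2L
  g1 <- exp(-((-half):half)^2 / (2 * sigma^2))
  wmat <- outer(g1, g1)
  wmat <- wmat / sum(wmat)
  C1 <- K1^2; C2 <- K2^2
  vals <- c()
  for (i in (half + 1L):(H - half)) {
    for (j in (half + 1L):(W - half)) {
      pa <- a[(i - half):(i + half), (j - half):(j + half)]
      pb <- b[(i - half):(i + half), (j - half):(j + half)]
      mua <- sum(wmat * pa); mub <- sum(wmat * pb)
      va <- sum(wmat * pa^2) - mua^2
      vb <- sum(wmat * pb^2) - mub^2
      cab <- sum(wmat * pa * pb) - mua * mub
      vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
                  ((mua^2 + mub^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

# Dense-kernel Gaussian blur with symmetric (reflect) padding, direct loops.
oracle_blur <- function(m, sigma) {
  H <- nrow(m); W <- ncol(m)
  radius <- max(1L, ceiling(4 * sigma))
  g1 <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k2 <- outer(g1, g1); k2 <- k2 / sum(k2)
  refl <- function(v, n) {
    period <- 2 * (n - 1)
    v <- (v - 1) %% period
    ifelse(v > (n - 1), period - v, v) + 1
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ri <- refl((i - radius):(i + radius), H)
      cj <- refl((j - radius):(j + radius), W)
      out[i, j] <- sum(k2 * m[ri, cj])
    }
  }
  out
}

# Naive inverse-map rotate+scale resampler (reflect padding, bilinear),
# written independently of the package's vectorized version.
oracle_geometric <- function(m, r_deg, s) {
  H <- nrow(m); W <- ncol(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  th <- r_deg * pi / 180
  refl <- function(v, n) {
    period <- 2 * (n - 1)
    v <- (v - 1) %% period
    if (v > (n - 1)) v <- period - v
    v + 1
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      dy <- (i - cy) / s; dx <- (j - cx) / s
      sr <- refl(cos(th) * dy - sin(th) * dx + cy, H)
      sc <- refl(sin(th) * dy + cos(th) * dx + cx, W)
      r0 <- min(floor(sr), H - 1); c0 <- min(floor(sc), W - 1)
      fr <- sr - r0; fc <- sc - c0
      out[i, j] <- m[r0, c0] * (1 - fr) * (1 - fc) +
        m[r0 + 1, c0] * fr * (1 - fc) +
        m[r0, c0 + 1] * (1 - fr) * fc +
        m[r0 + 1, c0 + 1] * fr * fc
    }
  }
  pmin(pmax(out, 0), 1)
}

# Cohen's kappa straight from a 2x2 contingency table of counts
# [[n_tt, n_tf], [n_ft, n_ff]].
oracle_kappa_from_counts <- function(counts) {
  n <- sum(counts)
  p_o <- (counts[1, 1] + counts[2, 2]) / n
  pa1 <- (counts[1, 1] + counts[1, 2]) / n
  pb1 <- (counts[1, 1] + counts[2, 1]) / n
  p_e <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  (p_o - p_e) / (1 - p_e)
}

# Exhaustive signed-rank null: enumerate all 2^n sign assignments of the
# observed midranks and compute the exact two-sided p for statistic v.
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  sums <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  p_lo <- mean(sums <= v_obs + 1e-9)
  p_hi <- mean(sums >= v_obs - 1e-9)
  list(v = v_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# Piecewise-constant band rendering from returned phantom geometry (hard
# edges, no vessels); used to bound boundary-induced column variation.
oracle_band_render <- function(truth) {
  H <- nrow(truth$clean); W <- ncol(truth$clean)
  nl <- length(truth$layer_reflectivities)
  bg <- truth$config$background
  out <- matrix(bg, H, W)
  for (x in seq_len(W)) {
    for (r in seq_len(H)) {
      if (r < truth$boundaries[1, x]) {
        out[r, x] <- bg
      } else if (r >= truth$boundaries[nl + 1, x]) {
        depth <- r - truth$boundaries[nl + 1, x]
        out[r, x] <- truth$config$choroid_value *
          exp(-truth$attenuation_rate * depth)
      } else {
        for (k in seq_len(nl)) {
          if (r >= truth$boundaries[k, x] && r < truth$boundaries[k + 1, x]) {
            out[r, x] <- truth$layer_reflectivities[k]
            break
          }
        }
      }
    }
  }
  pmin(pmax(out, 0), 1)
}

# A small cache so expensive fixtures (trained toy networks) are built once
# per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, make) {
  v <- .fixture_cache[[key]]
  if (is.null(v)) {
    v <- make()
    .fixture_cache[[key]] <- v
  }
  v
}

# Tiny trained denoiser + its dataset, reused by training/ensemble tests.
toy_trained_net <- function() {
  cached_fixture("toy_net", function() {
    ds <- make_paired_dataset(24, tiny_phantom_config(), seed = 11,
                              split = 0.75)
    net <- build_network(network_spec("brunet94", levels = 2,
                                      base_channels = 6), seed = 12)
    cfg <- train_config(epochs = 6, learning_rate = 1e-3, batch_size = 6,
                        augmentation = NULL, seed = 13)
    list(net = train_network(net, ds$train, cfg), data = ds)
  })
}

# Networks with distinct, non-trivial behaviour (randomized heads) for
# ensemble arithmetic tests.
distinct_nets <- function(n, seed = 5) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    net <- build_network(network_spec("brunet94", levels = 2,
                                      base_channels = 4), seed = 20 + i)
    net$params[["head.W"]][] <- rnorm(length(net$params[["head.W"]]), 0, 0.2)
    net$params[["head.b"]][] <- rnorm(1, 0, 0.05)
    net
  })
}
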