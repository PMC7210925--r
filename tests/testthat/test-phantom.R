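test_that("phantom generation is a pure function of config and seed", {
  a <- generate_clean_bscan(phantom_config(), 7)
  b <- generate_clean_bscan(phantom_config(), 7)
  expect_identical(as.matrix(a$clean), as.matrix(b$clean))
  expect_identical(a$boundaries, b$boundaries)
  c <- generate_clean_bscan(phantom_config(), 8)
  expect_gt(max(abs(as.matrix(a$clean) - as.matrix(c$clean))), 0)
})

test_that("phantom geometry invariants hold across seeds", {
  for (seed in 1:8) {
    t <- generate_clean_bscan(tiny_phantom_config(), seed)
    expect_true(all(diff(t$boundaries) >= 0))  # non-crossing curves
    expect_equal(length(t$layer_reflectivities), t$config$n_layers)
    m <- as.matrix(t$clean)
    expect_true(all(is.finite(m)) && min(m) >= 0 && max(m) <= 1)
  }
})

test_that("invalid phantom configs are rejected", {
  expect_error(phantom_config(height = 4), class = "octenhance_invalid")
  expect_error(phantom_config(n_layers = 1), class = "octenhance_invalid")
  expect_error(phantom_config(n_vessels = -1), class = "octenhance_invalid")
})

test_that("vessel-free phantoms match the band-render oracle per column", {
  t <- generate_clean_bscan(
    phantom_config(height = 48, width = 48, n_layers = 4, n_vessels = 0,
                   edge_softness = 0.5), 21)
  oracle <- oracle_band_render(t)
  col_diff <- abs(colMeans(as.matrix(t$clean)) - colMeans(oracle))
  # soft-edge rendering only disagrees with the hard-edged oracle within a
  # ~1 px transition band at each of the 5 boundaries
  expect_lt(max(col_diff), 0.05)
})

test_that("additive noise has the contracted distribution", {
  img <- bscan(matrix(0.5, 256, 256))
  expect_identical(add_noise(img, noise_spec("gaussian", 0), 1), img)
  sds <- vapply(1:10, function(s) {
    sd(as.matrix(add_noise(img, noise_spec("gaussian", 0.05), s)) - 0.5)
  }, numeric(1))
  expect_lt(abs(mean(sds) - 0.05) / 0.05, 0.02)

  zero <- bscan(matrix(0, 256, 256))
  means <- vapply(1:10, function(s) {
    mean(as.matrix(add_noise(zero, noise_spec("rayleigh", 0.2), s)))
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.2 * sqrt(pi / 2)) / (0.2 * sqrt(pi / 2)), 0.02)

  expect_error(noise_spec("poisson"), class = "octenhance_invalid")
  expect_error(noise_spec("gaussian", sigma = -1),
               class = "octenhance_invalid")
})

test_that("noise defaults follow the training-recipe scales", {
  expect_equal(noise_spec("gaussian")$sigma, 0.5)
  expect_equal(noise_spec("rayleigh")$sigma, 0.2)
})

test_that("frame averaging obeys the single-frame and sqrt(N) contracts", {
  truth <- generate_clean_bscan(phantom_config(), 31)
  one <- simulate_averaged_scan(truth, 1, noise_spec("gaussian", 0.1), 5)
  expect_identical(as.matrix(one$noisy), as.matrix(one$averaged))

  resid <- vapply(1:10, function(s) {
    ps <- simulate_averaged_scan(truth, 9, noise_spec("gaussian", 0.1), s)
    sd(as.matrix(ps$averaged) - as.matrix(ps$clean))
  }, numeric(1))
  expect_lt(abs(mean(resid) - 0.1 / 3) / (0.1 / 3), 0.15)

  expect_error(simulate_averaged_scan(truth, 0), class = "octenhance_invalid")
})

test_that("fixation jitter blurs the averaged scan", {
  truth <- generate_clean_bscan(phantom_config(), 41)
  ssims <- vapply(1:10, function(s) {
    still <- simulate_averaged_scan(truth, 9, noise_spec("gaussian", 0.1), s)
    shaky <- simulate_averaged_scan(
      truth, 9, noise_spec("gaussian", 0.1, jitter_px = 2), s)
    c(ssim(still$averaged, still$clean), ssim(shaky$averaged, shaky$clean))
  }, numeric(2))
  expect_lt(mean(ssims[2, ]), mean(ssims[1, ]))
})

test_that("paired datasets are deterministic, disjoint and well-formed", {
  d1 <- make_paired_dataset(10, tiny_phantom_config(), seed = 1, split = 0.8)
  d2 <- make_paired_dataset(10, tiny_phantom_config(), seed = 1, split = 0.8)
  expect_length(d1$train, 8)
  expect_length(d1$test, 2)
  expect_identical(as.matrix(d1$train[[1]]$noisy),
                   as.matrix(d2$train[[1]]$noisy))
  expect_identical(d1$manifest, d2$manifest)
  train_seeds <- d1$manifest$phantom_seed[d1$manifest$partition == "train"]
  test_seeds <- d1$manifest$phantom_seed[d1$manifest$partition == "test"]
  expect_length(intersect(train_seeds, test_seeds), 0)
  for (s in c(d1$train, d1$test)) {
    expect_identical(dim(s$noisy), dim(s$averaged))
    expect_identical(dim(s$noisy), dim(s$clean))
    expect_gte(s$n_frames, 1L)
    expect_true(max(s$noisy) <= 1 && min(s$noisy) >= 0)
  }
  expect_error(make_paired_dataset(1), class = "octenhance_invalid")
  expect_error(make_paired_dataset(10, split = 1.2),
               class = "octenhance_invalid")
})
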