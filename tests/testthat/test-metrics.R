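test_that("the noise estimator annihilates affine images and recovers sigma", {
  expect_identical(immerkaer_noise(matrix(0.37, 40, 40)), 0)
  plane <- outer(1:40, 1:40, function(r, c) (r + 2 * c) / 150)
  expect_lt(immerkaer_noise(plane), 1e-10)
  # translation invariance
  img <- rand_img(30, 30, seed = 2) * 0.5
  expect_equal(immerkaer_noise(img), immerkaer_noise(img + 0.3),
               tolerance = 1e-12)
  ests <- vapply(1:10, function(s) {
    set.seed(s)
    immerkaer_noise(matrix(rnorm(256^2, 0.5, 0.1), 256, 256))
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.1) / 0.1, 0.05)
  expect_error(immerkaer_noise(matrix(0, 2, 5)), class = "octenhance_invalid")
})

test_that("window SNR matches construction and is scale invariant", {
  set.seed(7)
  img <- matrix(0, 64, 64)
  img[40:60, ] <- 0.8                       # signal block
  img[1:20, ] <- 0.5 + rnorm(20 * 64, 0, 0.1)  # noise block
  img <- pmin(pmax(img, 0), 1)
  wp <- window_pair(signal_rows = c(40, 60), signal_cols = c(0, 64),
                    noise_rows = c(0, 20), noise_cols = c(0, 64))
  snr <- window_snr(img, wp)
  expect_lt(abs(snr - 8) / 8, 0.1)
  expect_equal(window_snr(img * 0.5, wp), snr, tolerance = 1e-12)
  expect_error(window_snr(matrix(0.5, 64, 64), wp),
               class = "octenhance_invalid")  # zero-variance noise window
})

test_that("window pairs validate geometry", {
  expect_error(window_pair(c(0, 2), c(0, 2), c(10, 20), c(10, 20)),
               class = "octenhance_invalid")  # too few pixels
  expect_error(window_pair(c(0, 10), c(0, 10), c(5, 15), c(5, 15)),
               class = "octenhance_invalid")  # overlap
  expect_error(window_pair(c(5, 5), c(0, 10), c(20, 30), c(0, 10)),
               class = "octenhance_invalid")  # empty interval
})

test_that("SSIM matches the sliding-window oracle and its contracts", {
  a <- rand_img(16, 16, seed = 1); b <- rand_img(16, 16, seed = 2)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_lt(abs(ssim(a, b) - oracle_ssim(a, b)), 1e-8)
  a2 <- rand_img(20, 14, seed = 3); b2 <- rand_img(20, 14, seed = 4)
  expect_lt(abs(ssim(a2, b2) - oracle_ssim(a2, b2)), 1e-8)
  expect_error(ssim(a, rand_img(8, 8)), class = "octenhance_invalid")
})

test_that("the analytic SSIM gradient matches finite differences", {
  a <- rand_img(16, 16, seed = 5) * 0.8 + 0.1
  b <- rand_img(16, 16, seed = 6) * 0.8 + 0.1
  sg <- octenhance:::ssim_with_grad(a, b)
  set.seed(9)
  for (t in 1:12) {
    i <- sample(16, 1); j <- sample(16, 1)
    e <- 1e-6
    ap <- a; ap[i, j] <- ap[i, j] + e
    am <- a; am[i, j] <- am[i, j] - e
    expect_lt(abs((ssim(ap, b) - ssim(am, b)) / (2 * e) - sg$grad[i, j]),
              1e-7)
  }
})

test_that("MAE is the mean absolute pixel difference", {
  x <- rand_img(9, 9, seed = 1)
  expect_identical(mae(x, x), 0)
  expect_identical(mae(matrix(c(0, 1), 1, 2), matrix(c(1, 0), 1, 2)), 1)
  y <- rand_img(9, 9, seed = 2)
  expect_equal(mae(x, y), mean(abs(x - y)), tolerance = 1e-12)
  expect_error(mae(x, rand_img(4, 4)), class = "octenhance_invalid")
})

test_that("paired t statistics match the closed form", {
  before <- c(10, 10, 10, 10, 10)
  after <- before + c(1, 2, 0, -1, 3)
  res <- paired_quality_stats(before, after)
  expect_equal(res$statistic, sqrt(2), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-sqrt(2), 4), tolerance = 1e-10)
  # jointly permuting pairs leaves t unchanged
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(paired_quality_stats(before[perm], after[perm])$statistic,
               res$statistic, tolerance = 1e-12)
  expect_error(paired_quality_stats(before, before + 2),
               class = "octenhance_invalid")  # zero-variance differences
})

test_that("quality reports assemble per-image metrics and paired tests", {
  ds <- make_paired_dataset(6, tiny_phantom_config(), seed = 3, split = 0.5)
  all_samples <- c(ds$train, ds$test)
  rep <- quality_report(
    original = lapply(all_samples, `[[`, "noisy"),
    enhanced = lapply(all_samples, `[[`, "averaged"),
    clean = lapply(all_samples, `[[`, "clean")
  )
  expect_equal(nrow(tidy(rep)), 12)
  expect_true(all(tidy(rep)$noise_estimate >= 0))
  nt <- dplyr::filter(glance(rep), metric == "noise_estimate")
  # 9-frame averaging must significantly reduce the estimated noise
  expect_lt(nt$mean_difference, 0)
  expect_lt(nt$p_value, 0.01)
})
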