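test_that("the reconstruction loss vanishes only at equality", {
  x <- rand_img(32, 32, seed = 1)
  expect_equal(reconstruction_loss(x, x), 0, tolerance = 1e-12)
  y <- rand_img(32, 32, seed = 2)
  expect_gt(reconstruction_loss(x, y), 0)
  expect_error(reconstruction_loss(x, rand_img(16, 16)),
               class = "octenhance_invalid")
  # MAE term on the printed 2x2 example: one 0.4 difference over 4 pixels
  expect_equal(mae(matrix(0, 2, 2), matrix(c(0.4, 0, 0, 0), 2, 2)), 0.1)
})

test_that("the loss matches an independent MAE + SSIM-dissimilarity oracle", {
  for (s in 1:3) {
    x <- rand_img(32, 32, seed = s)
    y <- rand_img(32, 32, seed = s + 10)
    expect_lt(abs(reconstruction_loss(x, y) -
                    (mean(abs(x - y)) + 1 - oracle_ssim(x, y))), 1e-6)
  }
})

test_that("training descends and is reproducible per seed", {
  ds <- make_paired_dataset(20, tiny_phantom_config(), seed = 5, split = 0.8)
  net <- build_network(network_spec("brunet94", levels = 2,
                                    base_channels = 6), seed = 6)
  cfg <- train_config(epochs = 5, learning_rate = 1e-3, batch_size = 4,
                      augmentation = NULL, seed = 7)
  t1 <- train_network(net, ds$train, cfg)
  expect_length(t1$history, 5)
  expect_lt(t1$history[5], t1$history[1])
  t2 <- train_network(net, ds$train, cfg)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params, t2$params)
  expect_error(train_network(net, list(), cfg), class = "octenhance_invalid")
})

test_that("training with on-the-fly augmentation runs and descends", {
  ds <- make_paired_dataset(12, tiny_phantom_config(), seed = 8, split = 0.75)
  net <- build_network(network_spec("brunet94", levels = 2,
                                    base_channels = 4), seed = 9)
  aug <- augmentation_config(noise = noise_spec("gaussian", sigma = 0.1))
  cfg <- train_config(epochs = 3, learning_rate = 1e-3, batch_size = 3,
                      augmentation = aug, seed = 10)
  tr <- train_network(net, ds$train, cfg)
  expect_length(tr$history, 3)
  expect_true(all(is.finite(tr$history)))
})

test_that("training defaults follow the published recipe", {
  cfg <- train_config()
  expect_identical(cfg$epochs, 500L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$augmentation$p_apply, 0.5)
})

test_that("an identity-trained residual network stays at zero loss", {
  ds <- make_paired_dataset(6, tiny_phantom_config(), seed = 11, split = 0.5)
  id_pairs <- lapply(ds$train, function(s) {
    s$noisy <- s$averaged  # target equals input
    s
  })
  net <- build_network(network_spec("brunet94", levels = 2,
                                    base_channels = 4), seed = 12)
  tr <- train_network(net, id_pairs,
                      train_config(epochs = 3, learning_rate = 1e-3,
                                   batch_size = 3, augmentation = NULL,
                                   seed = 13))
  expect_lt(max(tr$history), 1e-8)
})

test_that("fine-tuning continues from trained parameters", {
  fx <- toy_trained_net()
  cfg0 <- train_config(epochs = 0, augmentation = NULL, seed = 1)
  expect_identical(fine_tune(fx$net, fx$data$train, cfg0)$params,
                   fx$net$params)
  untrained <- build_network(network_spec("brunet94", levels = 2,
                                          base_channels = 6), seed = 1)
  expect_error(fine_tune(untrained, fx$data$train, cfg0),
               class = "octenhance_invalid")

  # fine-tuning on a new set reduces the loss on that set
  ds_b <- make_paired_dataset(12, tiny_phantom_config(), seed = 21,
                              split = 0.75,
                              noise = noise_spec("gaussian", sigma = 0.15))
  eval_loss <- function(net) {
    mean(vapply(ds_b$test, function(s) {
      reconstruction_loss(as.matrix(predict(net, s$noisy)),
                          as.matrix(s$averaged))
    }, numeric(1)))
  }
  before <- eval_loss(fx$net)
  tuned <- fine_tune(fx$net, ds_b$train,
                     train_config(epochs = 4, learning_rate = 1e-3,
                                  batch_size = 3, augmentation = NULL,
                                  seed = 22))
  expect_lt(eval_loss(tuned), before)
})

test_that("the four-variant ensemble recipe is expressible", {
  ds <- make_paired_dataset(8, tiny_phantom_config(), seed = 31, split = 0.5)
  cfg <- train_config(epochs = 2, learning_rate = 1e-3, batch_size = 2,
                      augmentation = NULL, seed = 32)
  net <- build_network(network_spec("brunet94", levels = 2,
                                    base_channels = 4), seed = 33)
  variants <- train_ensemble_variants(net, ds$train[1:2],
                                      set1 = ds$train[3:4],
                                      set2 = c(ds$test, ds$train[1:2])[1:2],
                                      config = cfg)
  expect_named(variants, c("base", "ft_set1", "ft_set2", "ft_all"))
  expect_true(all(vapply(variants, function(n) isTRUE(n$trained),
                         logical(1))))
  # fine-tuned members have drifted from the base parameters
  expect_false(identical(variants$base$params, variants$ft_set1$params))
})

test_that("degenerate distillation grids reduce to their members", {
  ds <- make_paired_dataset(4, tiny_phantom_config(), seed = 41, split = 0.5)
  cfg <- train_config(epochs = 2, learning_rate = 1e-3, batch_size = 2,
                      augmentation = NULL, seed = 42)
  spec <- network_spec("brunet94", levels = 2, base_channels = 4)
  g1 <- distill_grid(list(spec), list(base = ds$train),
                     list(noise_spec("gaussian", 0.2)), list(NULL))
  out1 <- distill_synthetic_set(g1, ds$train, cfg)
  expect_length(out1, length(ds$train))
  # grid of size 1: targets equal that single network's predictions
  cell_net <- local({
    cd <- purrr::map(ds$train, function(s) {
      structure(list(noisy = add_noise(s$clean, noise_spec("gaussian", 0.2),
                                       seed = (42L * 7919L) %% 2147483646L),
                     averaged = s$clean, clean = s$clean, n_frames = 1L),
                class = "paired_sample")
    })
    cfg1 <- cfg; cfg1$augmentation <- NULL
    train_network(build_network(spec, seed = cfg$seed), cd, cfg1)
  })
  expect_equal(as.matrix(out1[[1]]$averaged),
               as.matrix(predict(cell_net, ds$train[[1]]$noisy)),
               tolerance = 1e-12)

  # two identical cells: the mean of equal predictions is either prediction
  g2 <- distill_grid(list(spec), list(base = ds$train),
                     list(noise_spec("gaussian", 0.2)),
                     list(NULL, NULL))
  out2 <- distill_synthetic_set(g2, ds$train, cfg)
  expect_equal(as.matrix(out2[[1]]$averaged), as.matrix(out1[[1]]$averaged),
               tolerance = 1e-12)
})

test_that("a small distillation grid denoises most base images", {
  ds <- make_paired_dataset(22, tiny_phantom_config(), seed = 51,
                            split = 10 / 11)
  spec_a <- network_spec("brunet94", levels = 2, base_channels = 4)
  spec_b <- network_spec("unet", levels = 2, base_channels = 4)
  grid <- distill_grid(
    architectures = list(spec_a, spec_b),
    datasets = list(base = ds$train[1:10]),
    noise_models = list(noise_spec("gaussian", 0.1),
                        noise_spec("rayleigh", 0.1)),
    augmentation_tiers = list(NULL)
  )
  cfg <- train_config(epochs = 4, learning_rate = 1e-3, batch_size = 4,
                      augmentation = NULL, seed = 52)
  distilled <- distill_synthetic_set(grid, ds$train[1:10], cfg)
  expect_length(distilled, 10)
  reduced <- vapply(distilled, function(s) {
    immerkaer_noise(s$averaged) <= immerkaer_noise(s$noisy)
  }, logical(1))
  expect_gte(mean(reduced), 0.8)
})
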