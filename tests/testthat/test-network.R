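test_that("all four architecture families build and preserve shape/range", {
  specs <- list(
    network_spec("unet", upsampling = "transposed", levels = 3,
                 base_channels = 4),
    network_spec("unet", upsampling = "bilinear", levels = 3,
                 base_channels = 4),
    network_spec("brunet", levels = 3, base_channels = 4),
    network_spec("brunet94", levels = 3, base_channels = 4)
  )
  img <- rand_img(70, 90, seed = 1)  # not divisible by 2^(L-1)
  for (spec in specs) {
    net <- build_network(spec, seed = 1)
    out <- predict(net, img)
    expect_identical(dim(out), c(70L, 90L))
    expect_true(min(out) >= 0 && max(out) <= 1)
  }
})

test_that("forward passes are deterministic and reject non-finite input", {
  net <- build_network(network_spec("brunet94", levels = 3,
                                    base_channels = 8), seed = 2)
  img <- rand_img(64, 64, seed = 3)
  expect_identical(as.matrix(predict(net, img)), as.matrix(predict(net, img)))
  bad <- img; bad[1, 1] <- NA
  expect_error(predict(net, bad), class = "octenhance_invalid")
})

test_that("spec invariants are enforced", {
  expect_error(network_spec(levels = 1), class = "octenhance_invalid")
  expect_error(network_spec(base_channels = 0), class = "octenhance_invalid")
  expect_error(network_spec("brunet94", skip_mode = "concat"),
               class = "octenhance_invalid")
  expect_error(network_spec("unet", skip_mode = "sum"),
               class = "octenhance_invalid")
  # summation skips with unprojected bilinear upsampling cannot match
  # channel counts; the audit fails at construction time
  expect_error(
    build_network(network_spec("brunet94", levels = 3, base_channels = 8,
                               project_on_upsample = FALSE)),
    class = "octenhance_invalid")
})

test_that("parameter count matches the closed-form block arithmetic", {
  L <- 3L; base <- 8L
  net <- build_network(network_spec("brunet94", levels = L,
                                    base_channels = base), seed = 1)
  ch <- base * 2^(0:(L - 1))
  conv_pair <- function(cin, cout) {
    (9 * cin * cout + cout) + (9 * cout * cout + cout)
  }
  expected <- conv_pair(1, ch[1]) +                        # enc1
    conv_pair(ch[1] + 1, ch[2]) + conv_pair(ch[2] + 1, ch[3]) +  # enc2..3
    conv_pair(ch[3], ch[3]) +                              # horizontal block
    sum(vapply(1:(L - 1), function(k) {
      (ch[k + 1] * ch[k] + ch[k]) +                        # 1x1 projection
        conv_pair(ch[k], ch[k])                            # decoder pair
    }, numeric(1))) +
    (ch[1] * 1 + 1)                                        # output head
  expect_identical(count_parameters(net), as.integer(expected))
})

test_that("a freshly built residual-head network is the identity map", {
  net <- build_network(network_spec("brunet94", levels = 3,
                                    base_channels = 8), seed = 4)
  img <- rand_img(64, 64, seed = 5) * 0.98 + 0.01
  expect_equal(as.matrix(predict(net, img)), img, tolerance = 1e-14)
})

test_that("backpropagation matches finite differences for every layer type", {
  # brunet94 exercises sum skips + bilinear + projection + inject; the unet
  # variant exercises concat skips + transposed convolutions + max pooling.
  x <- rand_img(16, 16, seed = 6) * 0.8 + 0.1
  y <- rand_img(16, 16, seed = 7) * 0.8 + 0.1
  for (spec in list(network_spec("brunet94", levels = 2, base_channels = 3),
                    network_spec("unet", levels = 2, base_channels = 3,
                                 upsampling = "transposed"))) {
    net <- build_network(spec, seed = 8)
    net$params[["head.W"]][] <- rnorm(length(net$params[["head.W"]]), 0, 0.05)
    fw <- octenhance:::net_forward(net, x, train = TRUE)
    lg <- octenhance:::reconstruction_loss_grad(fw$out, y)
    G <- octenhance:::net_backward(net, fw, lg$grad)
    lossfn <- function(p) {
      n2 <- net; n2$params <- p
      octenhance:::reconstruction_loss_grad(
        octenhance:::net_forward(n2, x), y)$value
    }
    set.seed(10)
    # weight entries cover every backprop path; biases share those paths
    for (nm in grep("\\.W$", names(net$params), value = TRUE)) {
      for (t in 1:2) {
        i <- sample(length(net$params[[nm]]), 1)
        e <- 1e-6
        pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + e
        pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - e
        num <- (lossfn(pp) - lossfn(pm)) / (2 * e)
        expect_lt(abs(num - G[[nm]][i]), 1e-6)
      }
    }
  }
})

test_that("checkpoints round-trip a trained network exactly", {
  fx <- toy_trained_net()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_checkpoint(fx$net, path)
  back <- load_checkpoint(path)
  img <- fx$data$test[[1]]$noisy
  expect_equal(as.matrix(predict(back, img)), as.matrix(predict(fx$net, img)),
               tolerance = 1e-12)
  expect_identical(back$spec$family, "brunet94")
})
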