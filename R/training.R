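#' Training configuration
#'
#' Defaults follow the published recipe: 500 epochs with the Adam optimizer
#' at learning rate 0.0001, on-the-fly augmentation with 50% per-group
#' activation. Desk-scale runs override `epochs` (and typically raise the
#' learning rate to compensate for the compressed schedule; see the methods
#' vignette).
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param batch_size Mini-batch size (>= 1; default 8).
#' @param augmentation An [augmentation_config()], or `NULL` to train on
#'   the raw pairs.
#' @param seed Integer seed controlling shuffling and augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 500L, learning_rate = 1e-4,
                         batch_size = 8L,
                         augmentation = augmentation_config(), seed = 1L) {
  if (epochs < 0) stop_invalid("epochs must be >= 0")
  if (learning_rate <= 0) stop_invalid("learning_rate must be > 0")
  if (batch_size < 1) stop_invalid("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 augmentation = augmentation, seed = as.integer(seed)),
            class = "train_config")
}

#' Reconstruction loss: MAE plus SSIM dissimilarity
#'
#' `loss = MAE(output, target) + (1 - SSIM(output, target))`. Both terms
#' vanish iff the images are equal, so the loss is zero exactly at
#' equality. The SSIM term uses the standard dissimilarity form `1 - SSIM`
#' so that reducing structural difference reduces the loss.
#'
#' @param output,target Images of identical dimensions.
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(output, target) {
  output <- as.matrix(output); target <- as.matrix(target)
  if (!all(dim(output) == dim(target))) {
    stop_invalid("reconstruction loss: dimension mismatch")
  }
  mae(output, target) + (1 - ssim(output, target))
}

# Loss value and analytic gradient with respect to `output`.
reconstruction_loss_grad <- function(output, target) {
  n <- length(output)
  sg <- ssim_with_grad(output, target)
  list(value = mean(abs(output - target)) + (1 - sg$value),
       grad = sign(output - target) / n - sg$grad)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Coerce the various dataset containers to a plain list of paired samples.
as_sample_list <- function(dataset) {
  if (inherits(dataset, "paired_dataset")) return(dataset$train)
  if (inherits(dataset, "paired_sample")) return(list(dataset))
  dataset
}

#' Train an enhancement network
#'
#' Mini-batch gradient descent with Adam on the reconstruction loss,
#' mapping each noisy input frame to its N-frame averaged target.
#' Augmentation parameters are redrawn once per mini-batch; noise,
#' intensity and blur corrupt the input only, while geometric draws are
#' replayed identically on input and target so the pair stays registered.
#' Reproducible per `config$seed` under single-threaded BLAS.
#'
#' @param network An `oct_network` from [build_network()].
#' @param dataset A `paired_dataset` (its train split is used) or a list of
#'   `paired_sample`s.
#' @param config A [train_config()].
#' @return The trained network; `$history` holds the mean loss of each
#'   epoch (length `config$epochs`).
#' @export
train_network <- function(network, dataset, config = train_config()) {
  samples <- as_sample_list(dataset)
  if (length(samples) == 0) stop_invalid("empty training dataset")
  if (config$epochs == 0L) return(network)
  P <- network$params
  opt <- adam_init(P)
  history <- numeric(config$epochs)
  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(samples))
      batch_losses <- c()
      for (start in seq(1L, length(samples), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(samples))]
        draw <- if (!is.null(config$augmentation)) {
          sample_augmentation(config$augmentation,
                              sample.int(2147483646L, 1))
        }
        G <- NULL
        loss_sum <- 0
        net_tmp <- network; net_tmp$params <- P
        for (i in idx) {
          s <- samples[[i]]
          input <- s$noisy; target <- s$averaged
          if (!is.null(draw)) {
            input <- draw$apply_input(input)
            target <- draw$apply_target(target)
          }
          fw <- net_forward(net_tmp, as.matrix(input), train = TRUE)
          lg <- reconstruction_loss_grad(fw$out, as.matrix(target))
          if (!is.finite(lg$value)) {
            stop(sprintf("non-finite loss at epoch %d (sample %d)", epoch, i))
          }
          loss_sum <- loss_sum + lg$value
          gi <- net_backward(net_tmp, fw, lg$grad)
          G <- if (is.null(G)) gi else Map(`+`, G, gi)
        }
        G <- lapply(G, function(g) g / length(idx))
        st <- adam_step(P, G, opt, config$learning_rate)
        P <- st$params; opt <- st$state
        batch_losses <- c(batch_losses, loss_sum / length(idx))
      }
      history[epoch] <- mean(batch_losses)
    }
  })
  network$params <- P
  network$history <- c(network$history, history)
  network$trained <- TRUE
  network
}

#' Continue training a network on a new dataset
#'
#' Fine-tuning starts from the existing parameters (fresh optimizer state)
#' and otherwise behaves exactly like [train_network()]. Zero epochs
#' returns the network unchanged. The four-member inference ensemble of the
#' enhancement recipe is built from one base network via
#' [train_ensemble_variants()].
#'
#' @inheritParams train_network
#' @return The fine-tuned network.
#' @export
fine_tune <- function(network, dataset, config = train_config()) {
  if (!isTRUE(network$trained)) {
    stop_invalid("fine_tune expects an already trained network")
  }
  if (config$epochs == 0L) return(network)
  train_network(network, dataset, config)
}

#' Train the four-variant ensemble recipe
#'
#' Trains a base network on the synthetic (distilled) set, then derives the
#' four deployment variants: no fine-tune, fine-tuned on each of two device
#' sets, and fine-tuned on their union.
#'
#' @param network An untrained `oct_network`.
#' @param synthetic_set Distilled training pairs.
#' @param set1,set2 Device-specific fine-tuning datasets (lists of
#'   `paired_sample`s).
#' @param config A [train_config()] for the base run.
#' @param ft_config A [train_config()] for the fine-tuning runs.
#' @return List of four trained networks.
#' @export
train_ensemble_variants <- function(network, synthetic_set, set1, set2,
                                    config = train_config(),
                                    ft_config = config) {
  base <- train_network(network, synthetic_set, config)
  list(
    base = base,
    ft_set1 = fine_tune(base, set1, ft_config),
    ft_set2 = fine_tune(base, set2, ft_config),
    ft_all = fine_tune(base, c(as_sample_list(set1), as_sample_list(set2)),
                       ft_config)
  )
}

#' Distillation grid
#'
#' The cartesian grid of (architecture, dataset, noise model, augmentation
#' tier) cells used to distill a synthetic training set; the full-scale
#' recipe uses 4 architectures x 3 datasets x 2 noise models x
#' 3 augmentation tiers = 72 networks.
#'
#' @param architectures List of [network_spec()]s.
#' @param datasets Named list of datasets (lists of `paired_sample`s).
#' @param noise_models List of [noise_spec()]s.
#' @param augmentation_tiers List of [augmentation_config()]s (or `NULL`
#'   entries for no augmentation).
#' @return A `distill_grid`; its `cells` tibble enumerates the grid.
#' @export
distill_grid <- function(architectures, datasets, noise_models,
                         augmentation_tiers) {
  if (!length(architectures) || !length(datasets) || !length(noise_models) ||
      !length(augmentation_tiers)) {
    stop_invalid("every distillation grid axis must be non-empty")
  }
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("set", seq_along(datasets))
  }
  cells <- tidyr::expand_grid(
    arch = seq_along(architectures), dataset = names(datasets),
    noise = seq_along(noise_models), aug = seq_along(augmentation_tiers)
  )
  structure(list(architectures = architectures, datasets = datasets,
                 noise_models = noise_models,
                 augmentation_tiers = augmentation_tiers, cells = cells),
            class = "distill_grid")
}

#' Distill a synthetic training set from a grid of networks
#'
#' Trains one network per grid cell (each on its dataset's clean images
#' corrupted by the cell's noise model, under the cell's augmentation
#' tier), applies every trained network to every base image, and pixel-wise
#' averages the predictions. The result is a new paired dataset with the
#' original noisy inputs and the averaged predictions as targets; its size
#' equals the base dataset's.
#'
#' @param grid A [distill_grid()].
#' @param base_dataset List of `paired_sample`s to distill onto.
#' @param config A [train_config()] used for every cell.
#' @return List of `paired_sample`s with distilled targets.
#' @export
distill_synthetic_set <- function(grid, base_dataset,
                                  config = train_config()) {
  base <- as_sample_list(base_dataset)
  if (!length(base)) stop_invalid("empty base dataset")
  nets <- vector("list", nrow(grid$cells))
  for (ci in seq_len(nrow(grid$cells))) {
    cell <- grid$cells[ci, ]
    cfg <- config
    cfg$augmentation <- grid$augmentation_tiers[[cell$aug]]
    cell_noise <- grid$noise_models[[cell$noise]]
    # cells share the base seed: members differ by their content
    # (architecture, dataset, corruption), exactly as in the full recipe
    cell_data <- purrr::map(grid$datasets[[cell$dataset]], function(s) {
      corrupted <- add_noise(s$clean, cell_noise,
                             seed = (config$seed * 7919L) %% 2147483646L)
      structure(list(noisy = corrupted, averaged = s$clean, clean = s$clean,
                     n_frames = 1L), class = "paired_sample")
    })
    net <- build_network(grid$architectures[[cell$arch]], seed = config$seed)
    nets[[ci]] <- tryCatch(
      train_network(net, cell_data, cfg),
      error = function(e) {
        stop(sprintf("distillation cell %d (%s/%s/noise %d/aug %d) failed: %s",
                     ci, grid$architectures[[cell$arch]]$family,
                     cell$dataset, cell$noise, cell$aug, conditionMessage(e)))
      }
    )
  }
  purrr::map(base, function(s) {
    preds <- purrr::map(nets, function(net) as.matrix(predict(net, s$noisy)))
    target <- Reduce(`+`, preds) / length(preds)
    structure(list(noisy = s$noisy,
                   averaged = rewrap_bscan(clamp01(target), s$noisy,
                                           list(role = "distilled")),
                   clean = s$clean, n_frames = s$n_frames),
              class = "paired_sample")
  })
}
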