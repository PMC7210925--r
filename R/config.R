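#' Read and validate a run configuration
#'
#' The YAML configuration has optional sections `phantom`, `augmentation`,
#' `network`, `training`, `ensemble`, `metrics`, `paths` and a top-level
#' `seed`. Every section is validated against its constructor before any
#' work starts; validation failures name the offending section.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list with typed, validated sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  build <- function(section, constructor) {
    args <- raw[[section]] %||% list()
    tryCatch(
      do.call(constructor, args),
      error = function(e) {
        stop_invalid("config section '%s' invalid: %s", section,
                     conditionMessage(e))
      }
    )
  }
  noise_args <- raw$noise %||% list(model = "gaussian", sigma = 0.1)
  cfg <- list(
    seed = as.integer(raw$seed %||% 1L),
    phantom = build("phantom", phantom_config),
    noise = tryCatch(do.call(noise_spec, noise_args),
                     error = function(e) stop_invalid(
                       "config section 'noise' invalid: %s",
                       conditionMessage(e))),
    augmentation = build("augmentation", augmentation_config),
    network = build("network", network_spec),
    training = build("training", train_config),
    ensemble = raw$ensemble %||% list(use_histeq = TRUE),
    paths = raw$paths %||% list()
  )
  structure(cfg, class = "run_config")
}

#' Read a grading CSV
#'
#' Expects the exact schema
#' `image_id,grader_id,condition,IRF,SRF,ERM,Drusen,RPD,GA,iRORA,PED,HE,SCAR_FIB,quality`
#' with 0/1 (or TRUE/FALSE) biomarker flags; extra columns are ignored.
#'
#' @param path CSV path.
#' @return Tidy grading tibble for [agreement_report()].
#' @export
read_grading_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("grading CSV not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("image_id", "grader_id", "condition", BIOMARKERS, "quality")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_invalid("grading CSV lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  for (bm in BIOMARKERS) df[[bm]] <- as.logical(df[[bm]])
  tibble::as_tibble(df)
}

#' Write a grading table as CSV
#'
#' Inverse of [read_grading_csv()]: flags are written as 0/1.
#'
#' @param records Grading tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grading_csv <- function(records, path) {
  out <- as.data.frame(records)
  for (bm in BIOMARKERS) out[[bm]] <- as.integer(out[[bm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Format a numeric data frame for diff-able CSV output: '.' decimal,
# 6 significant digits.
write_metrics_csv <- function(df, path) {
  out <- as.data.frame(df)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a trained network to a self-describing checkpoint
#'
#' The checkpoint is plain YAML: the architecture spec, training history
#' and every parameter array (flattened, with dimensions), so a checkpoint
#' can be reloaded without knowing how it was configured.
#'
#' @param net An `oct_network`.
#' @param path Output path (conventionally `.yaml`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path) {
  payload <- list(
    spec = unclass(net$spec),
    history = net$history,
    trained = net$trained,
    seed = net$seed,
    params = lapply(net$params, function(p) {
      list(dim = dim(p) %||% length(p), data = as.numeric(p))
    })
  )
  yaml::write_yaml(payload, path, precision = 17)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path Checkpoint path written by [save_checkpoint()].
#' @return `load_checkpoint()`: the restored `oct_network`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_invalid("checkpoint not found: %s", path)
  payload <- yaml::read_yaml(path)
  spec <- do.call(network_spec, payload$spec)
  params <- lapply(payload$params, function(p) {
    array(as.numeric(p$data), unlist(p$dim))
  })
  structure(list(spec = spec, params = params,
                 history = as.numeric(payload$history %||% numeric(0)),
                 seed = payload$seed, trained = isTRUE(payload$trained)),
            class = "oct_network")
}
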