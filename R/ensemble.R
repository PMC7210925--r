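#' Global histogram equalization
#'
#' Monotone intensity remapping that flattens the global 256-bin histogram:
#' each pixel is mapped to the empirical CDF value of its bin, so output
#' values lie in `(0, 1]` with a near-uniform distribution. Constant images
#' are returned unchanged (there is no histogram to flatten).
#'
#' @param img A [bscan()] or matrix in `[0, 1]`.
#' @return Equalized image, same dimensions.
#' @export
histogram_equalize <- function(img) {
  img <- as_bscan(img)
  m <- unclass(img)
  if (max(m) - min(m) < .Machine$double.eps) return(img)
  bin <- pmin(floor(m * 256), 255)
  h <- tabulate(bin + 1L, 256L)
  cdf <- cumsum(h) / length(m)
  rewrap_bscan(matrix(cdf[bin + 1L], nrow(m), ncol(m)), img)
}

#' Test-time enhancement ensemble
#'
#' Bundles one to four trained networks. At inference each member is
#' applied to the unmodified input and (if `use_histeq`) to its
#' histogram-equalized variant; the deployment recipe uses four networks
#' times two input variants, i.e. the mean of eight images.
#'
#' @param members List of trained `oct_network`s (at least one).
#' @param use_histeq Also run every member on the histogram-equalized
#'   input.
#' @return An `oct_ensemble`.
#' @export
oct_ensemble <- function(members, use_histeq = TRUE) {
  if (inherits(members, "oct_network")) members <- list(members)
  if (!length(members)) stop_invalid("ensemble needs at least one member")
  ok <- vapply(members, inherits, logical(1), "oct_network")
  if (!all(ok)) stop_invalid("every ensemble member must be an oct_network")
  structure(list(members = members, use_histeq = isTRUE(use_histeq),
                 variant_count = length(members) *
                   (if (isTRUE(use_histeq)) 2L else 1L)),
            class = "oct_ensemble")
}

#' @export
print.oct_ensemble <- function(x, ...) {
  cat(sprintf("<oct_ensemble: %d member(s) x %s = %d variant images>\n",
              length(x$members),
              if (x$use_histeq) "2 input variants" else "1 input variant",
              x$variant_count))
  invisible(x)
}

#' Enhance a B-scan with an ensemble
#'
#' Applies every member network to the image and, if configured, to its
#' histogram-equalized variant, and returns the unweighted pixel-wise mean
#' of all variant outputs, clipped to `[0, 1]`. With a single member and no
#' equalized variant this reduces bit-exactly to the member's forward pass.
#' The output is invariant to member ordering.
#'
#' @param ensemble An [oct_ensemble()].
#' @param img A [bscan()] or matrix in `[0, 1]`.
#' @return Enhanced [bscan()], same dimensions as `img`.
#' @export
ensemble_enhance <- function(ensemble, img) {
  if (!inherits(ensemble, "oct_ensemble")) {
    stop_invalid("`ensemble` must be an oct_ensemble")
  }
  img <- as_bscan(img)
  variants <- list(img)
  if (ensemble$use_histeq) variants <- c(variants, list(histogram_equalize(img)))
  if (length(ensemble$members) == 1L && !ensemble$use_histeq) {
    return(predict(ensemble$members[[1L]], img))
  }
  acc <- NULL
  for (member in ensemble$members) {
    for (v in variants) {
      out <- as.matrix(predict(member, v))
      if (!is.null(acc) && !all(dim(out) == dim(acc))) {
        stop("ensemble member produced mismatched output dimensions")
      }
      acc <- if (is.null(acc)) out else acc + out
    }
  }
  rewrap_bscan(clamp01(acc / ensemble$variant_count), img,
               list(enhanced_by = sprintf("ensemble of %d",
                                          ensemble$variant_count)))
}
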