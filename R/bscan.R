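#' B-scan image objects
#'
#' A B-scan is a single grayscale OCT cross-section, stored as a numeric
#' matrix of intensities in `[0, 1]` (rows = depth, columns = lateral
#' position) with a free-form metadata list. All image-processing functions
#' in the package accept and return this currency.
#'
#' @param pixels Numeric matrix with finite values in `[0, 1]`, at least
#'   8 x 8.
#' @param meta Named list of free-form tags (device, seed, provenance).
#' @return A `bscan` object: the pixel matrix with class `"bscan"` and a
#'   `meta` attribute.
#' @examples
#' b <- bscan(matrix(0.5, 16, 16))
#' dim(b)
#' @export
bscan <- function(pixels, meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_invalid("`pixels` must be a numeric matrix")
  }
  validate_bscan_matrix(pixels)
  structure(pixels, class = c("bscan", class(matrix())), meta = meta)
}

validate_bscan_matrix <- function(pixels) {
  if (nrow(pixels) < 8 || ncol(pixels) < 8) {
    stop_invalid("B-scan must be at least 8 x 8 (got %d x %d)",
                 nrow(pixels), ncol(pixels))
  }
  if (!all(is.finite(pixels))) {
    stop_invalid("B-scan contains non-finite pixel values")
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop_invalid("B-scan intensities must lie in [0, 1] (range %.4g..%.4g)",
                 min(pixels), max(pixels))
  }
  invisible(pixels)
}

#' @rdname bscan
#' @param x Object to coerce or test.
#' @export
as_bscan <- function(x, meta = list()) {
  if (is_bscan(x)) return(x)
  bscan(as.matrix(x), meta = meta)
}

#' @rdname bscan
#' @export
is_bscan <- function(x) inherits(x, "bscan")

bscan_meta <- function(x) attr(x, "meta") %||% list()

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rewrap a plain matrix as a bscan, inheriting metadata from a template.
rewrap_bscan <- function(pixels, template = NULL, extra_meta = list()) {
  meta <- if (is.null(template)) list() else bscan_meta(template)
  meta[names(extra_meta)] <- extra_meta
  structure(pixels, class = c("bscan", class(matrix())), meta = meta)
}

#' @export
as.matrix.bscan <- function(x, ...) {
  m <- unclass(x)
  attr(m, "meta") <- NULL
  m
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan %d x %d, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Read a grayscale B-scan from PNG or TIFF
#'
#' Intensities are mapped linearly to `[0, 1]` by the file's bit depth; the
#' detected depth is recorded in `meta$bit_depth`. Color (multi-channel)
#' images are rejected: B-scans are single-channel by definition.
#'
#' @param path Path to an 8- or 16-bit grayscale PNG or TIFF file.
#' @return A [bscan()].
#' @export
read_bscan <- function(path) {
  if (!file.exists(path)) stop_invalid("file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path)
  } else {
    stop_invalid("unsupported image format '%s' (expect png/tif/tiff)", ext)
  }
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] > 1) {
      stop_invalid("multi-channel (color) image not supported: %s", path)
    }
    arr <- arr[, , 1]
  }
  # Both readers already rescale integer samples to [0,1] by bit depth; the
  # smallest positive increment reveals the stored depth.
  u <- sort(unique(as.vector(arr)))
  inc <- if (length(u) > 1) min(diff(u)) else 1
  depth <- if (inc < 1 / 260) 16L else 8L
  bscan(clamp01(arr), meta = list(path = path, bit_depth = depth))
}

#' Write a B-scan as PNG or TIFF
#'
#' Encoding is deterministic: intensities are scaled by `2^bit_depth - 1`
#' and rounded half-to-even (base R `round()`), so the same image always
#' produces byte-identical files. PNG output is 8-bit (the limit of the PNG
#' writer); 16-bit output uses TIFF.
#'
#' @param img A [bscan()] (or matrix in `[0, 1]`).
#' @param path Output path; extension selects PNG or TIFF.
#' @param bit_depth 8 or 16 (16 requires a `.tif`/`.tiff` path).
#' @return `path`, invisibly.
#' @export
write_bscan <- function(img, path, bit_depth = 16) {
  img <- as_bscan(img)
  if (!bit_depth %in% c(8, 16)) stop_invalid("bit_depth must be 8 or 16")
  ext <- tolower(tools::file_ext(path))
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  scale <- 2^bit_depth - 1
  m <- round(m * scale) / scale
  if (ext == "png") {
    if (bit_depth != 8) {
      stop_invalid("PNG output is 8-bit; use a .tif path for bit_depth = 16")
    }
    png::writePNG(m, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, where = path, bits.per.sample = bit_depth,
                    compression = "none")
  } else {
    stop_invalid("unsupported image format '%s' (expect png/tif/tiff)", ext)
  }
  invisible(path)
}
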