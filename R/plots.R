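#' Plot a B-scan
#'
#' Raster display in the conventional orientation (shallow depth at the
#' top).
#'
#' @param object A [bscan()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bscan <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$intensity <- as.vector(unclass(object))[
    (df$col - 1L) * nrow(object) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "lateral position (px)", y = "depth (px)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a training loss history
#'
#' @param object A trained `oct_network`.
#' @param ... Unused.
#' @return A ggplot of mean epoch loss.
#' @exportS3Method ggplot2::autoplot
autoplot.oct_network <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean reconstruction loss (MAE + 1 - SSIM)") +
    ggplot2::theme_minimal()
}

#' Plot intergrader agreement by biomarker
#'
#' @param object An `oct_agreement` from [agreement_report()].
#' @param ... Unused.
#' @return A ggplot of kappa per biomarker, original vs enhanced.
#' @exportS3Method ggplot2::autoplot
autoplot.oct_agreement <- function(object, ...) {
  ggplot2::ggplot(object$kappa,
                  ggplot2::aes(.data$biomarker, .data$kappa,
                               colour = .data$condition)) +
    ggplot2::geom_point(size = 2.5,
                        position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = "Cohen's kappa", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-image quality metrics, original vs enhanced
#'
#' @param object A `quality_report` from [quality_report()].
#' @param metric One of the per-image metric columns.
#' @param ... Unused.
#' @return A ggplot (paired boxplot).
#' @exportS3Method ggplot2::autoplot
autoplot.quality_report <- function(object, metric = "noise_estimate", ...) {
  ggplot2::ggplot(object$per_image,
                  ggplot2::aes(.data$condition, .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
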