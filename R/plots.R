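#' Plot a length normalization against the original encoding
#'
#' Draws the encoded sequence (solid line over positions `1..L`) together
#' with its resampled version of length `dims` (dashed, placed on the
#' target grid `1 + (j-1)(L-1)/(dims-1)` so the two curves share an axis).
#'
#' @param values Numeric vector: the encoded sequence.
#' @param dims Target length.
#' @param method Interpolation method (see [interpolation_methods()]).
#' @param ... Passed to [resample()].
#' @return A ggplot object.
#' @examples
#' enc <- encode_sequence(strrep("CTRPNNNTRKSIHIGPGRAFYTTGEIIGDIRQAHCNIS", 1),
#'                        normalize = "unit")
#' plot_interpolation(as.numeric(enc), 35, method = "spline")
#' @export
plot_interpolation <- function(values, dims, method = "linear", ...) {
  L <- length(values)
  out <- resample(values, dims, method = method, ...)
  df <- dplyr::bind_rows(
    tibble(x = seq_len(L), y = as.numeric(values),
           series = sprintf("original (L = %d)", L)),
    tibble(x = 1 + (seq_len(dims) - 1) * (L - 1) / (dims - 1), y = out,
           series = sprintf("normalized (D = %d, %s)", dims, method)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   linetype = .data$series)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "sequence position", y = "descriptor value",
                  linetype = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' @describeIn demo_classification ROC curve of the cross-validated demo
#'   classifier.
#' @param object A `demo_classification` object.
#' @export
autoplot.demo_classification <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%d-fold CV, AUC = %.3f", object$folds,
                                  object$auc)) +
    ggplot2::theme_minimal()
}

#' @describeIn build_feature_matrix Heatmap of a feature matrix (sequences
#'   by normalized position).
#' @param object A `feature_matrix`.
#' @export
autoplot.feature_matrix <- function(object, ...) {
  long <- tidy.feature_matrix(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$position,
                                     factor(.data$id, levels = rev(unique(.data$id))),
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "normalized position", y = NULL,
                  fill = "descriptor\nvalue") +
    ggplot2::theme_minimal()
}
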