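#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC or PR curve
#'
#' @param object a `curve_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.curve_result <- function(object, ...) {
  if (object$type == "roc") {
    ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_path() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                    title = sprintf("ROC curve (AUC = %.3f)", object$area))
  } else {
    ggplot2::ggplot(object$points,
                    ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_path() +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("PR curve (AP = %.3f)", object$area))
  }
}

#' Plot the training loss history
#'
#' @param object an `octdistill_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.octdistill_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$mean_loss)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Epoch", y = "Mean distillation loss",
                  title = "Student training history")
}

#' Plot an anomaly explanation map
#'
#' @param object an `anomaly_map` matrix.
#' @param ... unused.
#' @return a ggplot raster of per-pixel anomaly intensity.
#' @export
autoplot.anomaly_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$value <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "anomaly") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = "Anomaly explanation map")
}

#' Plot the severity association
#'
#' @param object an `octdistill_severity`.
#' @param ... unused.
#' @return a ggplot of map score vs relative lesion area.
#' @export
autoplot.octdistill_severity <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$relative_lesion_area,
                               y = .data$map_score)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Relative lesion area", y = "Anomaly-map severity score",
                  title = sprintf("Severity association (Spearman rho = %.2f)",
                                  object$spearman))
}

#' Plot relative-position anomaly profiles
#'
#' @param profile_data output of [anomaly_profile()].
#' @return a ggplot of mean score against relative B-scan position, one line
#'   per class.
#' @export
plot_anomaly_profile <- function(profile_data) {
  ggplot2::ggplot(profile_data,
                  ggplot2::aes(x = .data$position, y = .data$mean_score,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Relative B-scan position", y = "Mean anomaly score",
                  colour = NULL, title = "Anomaly profiles")
}

#' Show a B-scan with an optional anomaly-map overlay
#'
#' @param image grayscale B-scan matrix.
#' @param map optional anomaly map of the same shape; drawn as a transparent
#'   heat overlay.
#' @param alpha maximum overlay opacity.
#' @return a ggplot.
#' @export
plot_bscan <- function(image, map = NULL, alpha = 0.5) {
  df <- tidyr::expand_grid(row = seq_len(nrow(image)),
                           col = seq_len(ncol(image)))
  df$intensity <- as.vector(image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
  if (!is.null(map)) {
    df2 <- df
    df2$anom <- as.vector(unclass(map))
    rng <- range(df2$anom)
    df2$a <- if (rng[2] > rng[1]) (df2$anom - rng[1]) / (rng[2] - rng[1]) else 0
    p <- p + ggplot2::geom_raster(data = df2,
                                  ggplot2::aes(alpha = .data$a),
                                  fill = "red") +
      ggplot2::scale_alpha_identity()
    p <- p + ggplot2::labs(title = "B-scan with anomaly overlay")
  }
  p
}
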