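#' Heatmap of a connectivity matrix
#'
#' @param m A `connectivity_matrix` (or any symmetric matrix).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_connectivity <- function(m, title = NULL) {
  n <- nrow(m)
  labs <- rownames(m)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  df <- tidyr::expand_grid(row = seq_len(n), col = seq_len(n))
  df$weight <- unclass(m)[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "r", title = title) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_connectivity autoplot method
#' @param object A `connectivity_matrix`.
#' @param ... Unused.
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  plot_connectivity(object, title = attr(object, "subject_id"))
}

#' ROC curve plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- object$curve[order(1 - object$curve$specificity,
                              object$curve$sensitivity), ]
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity,
                                      y = .data$sensitivity)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f (p = %.3g)", object$auc,
                                  object$p_auc)) +
    ggplot2::theme_minimal()
}

#' Null distribution of the distance resampling test
#'
#' @param object A `distance_null_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_null_result <- function(object, ...) {
  df <- tibble::tibble(null_mean = object$null_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_mean)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_mean, colour = "red") +
    ggplot2::labs(x = "Null mean anatomical distance (mm)", y = "Draws",
                  title = sprintf("Observed %.1f mm, empirical p = %.4g",
                                  object$observed_mean, object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' Edge-level t statistics of an NBS result
#'
#' Heatmap of the masked edge-wise t matrix with the leading component's
#' edges outlined.
#'
#' @param object An `nbs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbs_result <- function(object, ...) {
  n <- nrow(object$t_matrix)
  df <- tidyr::expand_grid(row = seq_len(n), col = seq_len(n))
  df$t <- object$t_matrix[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$t)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  na.value = "grey92") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "t") +
    ggplot2::theme_minimal()
  if (length(object$components) > 0) {
    comp <- object$components[[1]]$edges
    hl <- dplyr::bind_rows(
      tibble::tibble(row = comp$i, col = comp$j),
      tibble::tibble(row = comp$j, col = comp$i))
    p <- p + ggplot2::geom_tile(data = hl,
                                ggplot2::aes(x = .data$col, y = .data$row),
                                inherit.aes = FALSE, fill = NA,
                                colour = "black", linewidth = 0.3)
  }
  p
}
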