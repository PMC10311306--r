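#' Plot a WCSS curve with its elbow
#'
#' @param curve a tibble with columns `k` and `wcss`, or a
#'   `cluster_report`.
#' @param chosen_k optional k to mark; taken from the report when given.
#' @return A ggplot object.
#' @export
plot_wcss <- function(curve, chosen_k = NULL) {
  if (inherits(curve, "cluster_report")) {
    chosen_k <- curve$chosen_k
    curve <- curve$wcss_curve
  }
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$wcss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = curve$k) +
    ggplot2::labs(x = "number of clusters k",
                  y = "within-cluster sum of squares") +
    ggplot2::theme_minimal()
  if (!is.null(chosen_k) && chosen_k %in% curve$k) {
    p <- p + ggplot2::geom_vline(xintercept = chosen_k, linetype = "dashed")
  }
  p
}

#' Scatter the combined (noisy) coordinates
#'
#' First two coordinates of the server-side combined points, colored by
#' cluster assignment when a report is given, otherwise by source
#' researcher.
#'
#' @param points a `combined_points` tibble.
#' @param report optional `cluster_report` for the same points.
#' @return A ggplot object.
#' @export
plot_combined_points <- function(points, report = NULL) {
  df <- tibble::as_tibble(points)
  coord_cols <- grep("^coord_[0-9]+$", names(df), value = TRUE)[1:2]
  df$.x <- df[[coord_cols[1]]]
  df$.y <- df[[coord_cols[2]]]
  if (!is.null(report)) {
    df$cluster <- factor(report$assignments$cluster[
      match(df$hashed_id, report$assignments$id)])
    aes <- ggplot2::aes(x = .data$.x, y = .data$.y,
                        color = .data$cluster, shape = .data$source)
  } else {
    aes <- ggplot2::aes(x = .data$.x, y = .data$.y, color = .data$source)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "PC1 (noisy)", y = "PC2 (noisy)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cluster_report <- function(object, ...) {
  if (nrow(object$wcss_curve) > 1) plot_wcss(object)
  else {
    ggplot2::ggplot(object$cluster_sizes,
                    ggplot2::aes(x = factor(.data$cluster), y = .data$size)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "cluster", y = "size") +
      ggplot2::theme_minimal()
  }
}

#' @export
autoplot.attack_result <- function(object, ...) {
  df <- tidy.attack_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$min_distance, fill = .data$set)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "minimum distance / statistic", y = "count",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.experiment_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary,
                            c("precision", "recall", "power"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epsilon, y = .data$value,
                                   color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(epsilon), y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
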