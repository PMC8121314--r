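raster_df <- function(m, value = "value") {
  H <- nrow(m)
  d <- expand.grid(row = seq_len(H), col = seq_len(ncol(m)))
  d[[value]] <- as.vector(m)
  d
}

#' Plot an en-face image, mask or skeleton
#'
#' @param object an [enface] object (for `autoplot`) or a matrix (for
#'   `plot_matrix_image()`).
#' @param ... unused.
#' @return A ggplot object (row 1 rendered at the top, matching the
#'   image convention).
#' @export
autoplot.enface <- function(object, ...) {
  plot_matrix_image(object$pixels) +
    ggplot2::labs(title = sprintf("%s (%s)", object$eye_id, object$laterality))
}

#' @rdname autoplot.enface
#' @export
plot_matrix_image <- function(object, ...) {
  d <- raster_df(if (is.logical(object)) object * 255 else object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Overlay of classified vessel segments
#'
#' Draws the skeleton segments over the vessel mask, colored by oblique
#' class: natural in blue, unnatural in red, neither in gray, with the
#' watershed midline dashed.
#'
#' @param segments tibble from [extract_segments()].
#' @param mask optional vessel mask drawn underneath.
#' @return A ggplot object.
#' @export
plot_segments <- function(segments, mask = NULL) {
  H <- attr(segments, "height")
  seg_df <- dplyr::bind_rows(lapply(seq_len(nrow(segments)), function(i) {
    p <- segments$path[[i]]
    data.frame(
      segment_id = segments$segment_id[i],
      row = p[, 1], col = p[, 2],
      class = classify_oblique(segments$orientation_deg[i],
                               segments$region[i])
    )
  }))
  g <- ggplot2::ggplot()
  if (!is.null(mask)) {
    md <- raster_df(mask * 1)
    g <- g + ggplot2::geom_raster(
      data = md[md$value > 0, ],
      ggplot2::aes(x = .data$col, y = .data$row), fill = "gray85"
    )
  }
  g +
    ggplot2::geom_path(
      data = seg_df,
      ggplot2::aes(x = .data$col, y = .data$row,
                   group = .data$segment_id, color = .data$class),
      linewidth = 0.6
    ) +
    ggplot2::geom_hline(yintercept = (H %||% max(seg_df$row)) / 2,
                        linetype = "dashed", color = "gray40") +
    ggplot2::scale_color_manual(values = c(
      natural = "#2166ac", unnatural = "#b2182b", neither = "gray60"
    )) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(color = "oblique class")
}

#' ROC curves of a cross-validated comparison
#'
#' Pools the out-of-fold confidence scores of each model and draws its
#' ROC curve (asymmetry positive).
#'
#' @param object a `choro_cv` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.choro_cv <- function(object, ...) {
  roc_df <- object$scores |>
    dplyr::group_by(.data$model) |>
    dplyr::group_modify(function(d, key) {
      sc <- 1 - d$cs
      pos <- d$label == "asymmetric"
      ord <- order(sc, decreasing = TRUE)
      tpr <- cumsum(pos[ord]) / sum(pos)
      fpr <- cumsum(!pos[ord]) / sum(!pos)
      tibble(fpr = c(0, fpr), tpr = c(0, tpr))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(roc_df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       color = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "gray50") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "Pooled cross-validated ROC") +
    ggplot2::theme_minimal()
}

#' Stacked confidence-bin breakdown per agreement group
#'
#' @param object a `choro_crosstab` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.choro_crosstab <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$pct,
                                       fill = .data$bin)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(
      unconfident = "#d73027", moderately_confident = "#fee08b",
      confident = "#1a9850"
    )) +
    ggplot2::labs(x = NULL, y = "% of eyes in group", fill = "AI confidence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Best-fitness trajectory of a feature-selection run
#'
#' @param object a `choro_gafs` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.choro_gafs <- function(object, ...) {
  d <- tibble(generation = seq_along(object$fitness_history),
              fitness = object$fitness_history)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best CV accuracy") +
    ggplot2::theme_minimal()
}
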