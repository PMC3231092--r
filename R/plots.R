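#' Plot detected wall boundaries
#'
#' Detected intima and adventitia rows per column for a subset of frames.
#' The y axis is reversed so the plot matches image orientation (rows
#' increase downward).
#'
#' @param object a `wall_result`.
#' @param frames frame indices to show (default: up to 4, evenly spaced).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.wall_result <- function(object, frames = NULL, ...) {
  tr <- object$traces
  if (is.null(frames)) {
    all_f <- sort(unique(tr$frame))
    frames <- all_f[unique(round(seq(1, length(all_f), length.out = min(4, length(all_f)))))]
  }
  tr <- tr[tr$frame %in% frames, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$column, y = .data$row,
                                   colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~frame, labeller = ggplot2::label_both) +
    ggplot2::labs(title = sprintf("%s wall boundaries", object$wall),
                  x = "column (px)", y = "row (px)")
}

#' Plot the lumen-diameter waveform
#'
#' Per-frame mean lumen diameter in mm across the sequence.
#'
#' @param object a `lumen_series`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lumen_series <- function(object, ...) {
  ggplot2::ggplot(object$per_frame,
                  ggplot2::aes(x = .data$frame, y = .data$mean_ld_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "frame", y = "mean lumen diameter (mm)",
                  title = "Lumen diameter over the cardiac cycles")
}

#' Plot a feature map
#'
#' Gray-level raster of a feature or cost map in image orientation.
#'
#' @param x a `cawall_feature` or numeric matrix.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot_feature_map <- function(x, ...) {
  df <- tidyr::expand_grid(column = seq_len(ncol(x)), row = seq_len(nrow(x)))
  df$value <- as.vector(unclass(x))  # column-major matches row-fastest grid
  ggplot2::ggplot(df, ggplot2::aes(.data$column, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = attr(x, "provenance") %||% "value")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
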