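#' Plot an angle map
#'
#' Vessel pixels are coloured by angle; background is left blank. For
#' radial-relative maps, low angles (radiating vessels) map to blue and
#' angles near 90 degrees (concentric) to red.
#'
#' @param object An `angle_map`.
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.angle_map <- function(object, ...) {
  idx <- which(object$mask, arr.ind = TRUE)
  df <- tibble(
    row = idx[, 1], col = idx[, 2],
    angle = object$angles[idx]
  )
  top <- if (object$convention == "radial_relative") 90 else 179
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$angle)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(
      colours = c("blue", "cyan", "green", "yellow", "red"),
      limits = c(0, top), name = "angle [deg]"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = object$convention) +
    ggplot2::theme_minimal()
}

#' Plot a grayscale image
#'
#' @param object A [gray_image()].
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.gray_image <- function(object, ...) {
  m <- unclass(object)
  df <- tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    intensity = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
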