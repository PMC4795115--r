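#' Plot a profile map as a position-by-profile heat map
#'
#' @param object A `profile_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.profile_map <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(as.data.frame(object$values),
                  position = object$positions),
    -"position", names_to = "profile", values_to = "intensity")
  df$profile <- as.integer(factor(df$profile, levels = unique(df$profile)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$profile, y = .data$position,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intensity (a.u.)") +
    ggplot2::labs(x = "profile", y = "normalized position",
                  title = sprintf("Profile map (%s)", object$stage)) +
    ggplot2::theme_minimal()
}

#' Plot an average profile with its SD band
#'
#' @param object An `average_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.average_profile <- function(object, ...) {
  df <- tibble::tibble(position = object$position, mean = object$mean,
                       sd = object$sd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "normalized position", y = "fluorescence (a.u.)",
                  title = sprintf("Average profile (%s, n = %d)",
                                  attr(object, "stage"), attr(object, "n"))) +
    ggplot2::theme_minimal()
}

#' Plot a virtual cell
#'
#' @param object A `virtual_cell`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.virtual_cell <- function(object, ...) {
  img <- object$cartesian
  df <- expand.grid(row = seq_len(nrow(img)) - 1L,
                    col = seq_len(ncol(img)) - 1L)
  df$intensity <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(title = sprintf("Virtual cell (%s)", object$enhancement),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @export
plot.profile_map <- function(x, ...) print(autoplot.profile_map(x, ...))

#' @export
plot.average_profile <- function(x, ...) {
  print(autoplot.average_profile(x, ...))
}

#' @export
plot.virtual_cell <- function(x, ...) print(autoplot.virtual_cell(x, ...))
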