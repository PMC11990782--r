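#' Plot scenario trajectories
#'
#' Ground-truth box-centre trajectories in camera coordinates, coloured
#' by identity, with occluded stretches drawn hollow.
#'
#' @param object A `mot_scenario`.
#' @param world Plot world coordinates instead of camera coordinates.
#' @param ... Unused.
#' @return A ggplot object (y axis flipped to image convention).
#' @method autoplot mot_scenario
#' @export
autoplot.mot_scenario <- function(object, world = FALSE, ...) {
  gt <- if (world) object$gt_world else object$gt
  df <- dplyr::left_join(gt, object$occluded, by = c("frame", "id")) |>
    dplyr::mutate(cx = .data$left + .data$width / 2,
                  cy = .data$top + .data$height / 2,
                  id = factor(.data$id))
  ggplot2::ggplot(df, ggplot2::aes(.data$cx, .data$cy, colour = .data$id,
                                   group = .data$id)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$occluded), size = 1) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "identity",
                  shape = "occluded",
                  title = if (world) "world trajectories"
                          else "camera-frame trajectories")
}

#' Plot tracked trajectories
#'
#' @param object A `mot_tracking` object from [track()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mot_tracking
#' @export
autoplot.mot_tracking <- function(object, ...) {
  df <- dplyr::mutate(object$results,
                      cx = .data$left + .data$width / 2,
                      cy = .data$top + .data$height / 2,
                      id = factor(.data$id))
  ggplot2::ggplot(df, ggplot2::aes(.data$cx, .data$cy, colour = .data$id,
                                   group = .data$id)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "track",
                  title = "tracked trajectories")
}

#' Bar chart of an evaluation report
#'
#' @param object A `mot_metrics` object.
#' @param ... Unused.
#' @return A ggplot object showing MOTA / MOTP / IDF1 as percentages.
#' @method autoplot mot_metrics
#' @export
autoplot.mot_metrics <- function(object, ...) {
  df <- tibble::tibble(metric = c("MOTA", "MOTP", "IDF1"),
                       value = 100 * c(object$mota, object$motp,
                                       object$idf1))
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "%", title = "tracking quality")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
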