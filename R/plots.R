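#' Map block-group exposure labels
#'
#' Draws the block-group polygons filled by exposure class, optionally
#' overlaying facility locations.
#'
#' @param block_groups Block-group tibble with `geometry`.
#' @param exposure Output of [classify_air()] or [classify_landwater()].
#' @param label_col Which label column to map (default: whichever of
#'   `air_label` / `landwater_label` is present).
#' @param facilities Optional facility tibble to overlay as points.
#' @return A ggplot object.
#' @export
plot_exposure_map <- function(block_groups, exposure, label_col = NULL,
                              facilities = NULL) {
  check_columns(block_groups, c("block_group_id", "geometry"), "block_groups")
  label_col <- label_col %||%
    intersect(c("air_label", "landwater_label"), names(exposure))[1]
  if (is.na(label_col)) abort("`exposure` has no label column.")
  df <- dplyr::inner_join(block_groups, exposure, by = "block_group_id")
  poly <- purrr::map2_dfr(df$block_group_id, df$geometry, function(id, g) {
    g <- close_ring(g)
    tibble(block_group_id = id, x = g[, 1], y = g[, 2])
  })
  poly <- dplyr::left_join(
    poly, df[, c("block_group_id", label_col)], by = "block_group_id")
  p <- ggplot2::ggplot(poly, ggplot2::aes(x = .data$x, y = .data$y,
                                          group = .data$block_group_id,
                                          fill = .data[[label_col]])) +
    ggplot2::geom_polygon(colour = "white", linewidth = 0.1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km", y = "km", fill = NULL)
  if (!is.null(facilities)) {
    p <- p + ggplot2::geom_point(
      data = facilities,
      ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, shape = 17, size = 2)
  }
  p
}

#' @export
autoplot.air_summary <- function(object, ...) {
  ggplot2::ggplot(object$by_facility_type,
                  ggplot2::aes(x = .data$period_label, y = .data$n_events,
                               fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "events", fill = "facility type")
}

#' @export
autoplot.landwater_summary <- function(object, ...) {
  ggplot2::ggplot(object$by_source_type,
                  ggplot2::aes(x = .data$period_label, y = .data$n_reports,
                               fill = .data$source_type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "reports", fill = "source type")
}
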