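#' Plot an annual growth table
#'
#' New entries per year as bars with the cumulative count as a line on a
#' secondary axis, the conventional display of database growth.
#'
#' @param object A `growth_tbl` from [growth_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_tbl <- function(object, ...) {
  entity <- attr(object, "entity", exact = TRUE) %||% "entities"
  scale <- max(object$n_new, 1, na.rm = TRUE) / max(object$n_cumulative, 1)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_new), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$n_cumulative * scale),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::scale_y_continuous(
      name = sprintf("new %s per year", entity),
      sec.axis = ggplot2::sec_axis(~ . / scale, name = sprintf("cumulative %s", entity))
    ) +
    ggplot2::labs(x = "year") +
    ggplot2::theme_minimal()
}

#' Plot mean promiscuity over time
#'
#' @param object An `annual_promiscuity` tibble from
#'   [annual_mean_promiscuity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.annual_promiscuity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$mean_degree)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(x = "year", y = "mean promiscuity degree (targets/compound)") +
    ggplot2::theme_minimal()
}

#' Plot a delta-promiscuity histogram
#'
#' @param object A `delta_histogram` from [delta_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.delta_histogram <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      bin = factor(.data$bin, levels = delta_bins()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "gain in target annotations (delta promiscuity)",
                  y = "compounds") +
    ggplot2::theme_minimal()
}
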