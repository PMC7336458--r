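#' Plot a colored optical map
#'
#' Draws each map as a horizontal bar of fragments along genomic
#' coordinates, filled by color index; uncolored fragments are grey.
#'
#' @param maps A stacked (optionally colored) map tibble.
#' @return A ggplot object.
#' @export
plot_colored_map <- function(maps) {
  df <- maps |>
    group_by(.data$map_id) |>
    arrange(.data$fragment, .by_group = TRUE) |>
    mutate(xend = cumsum(.data$length), x = .data$xend - .data$length) |>
    ungroup()
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$x, xmax = .data$xend, ymin = 0, ymax = 1,
      fill = .data$color
    ), colour = "white", linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$map_id)) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = "color") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
}

#' Block diagram of an optical-map alignment
#'
#' Shows each alignment block as a rectangle spanning its query and
#' reference fragment ranges.
#'
#' @param object An `om_alignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.om_alignment <- function(object, ...) {
  b <- object$blocks
  ggplot2::ggplot(b) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$r_from - 0.5, xmax = .data$r_to + 0.5,
      ymin = .data$q_from - 0.5, ymax = .data$q_to + 0.5
    ), fill = "steelblue", alpha = 0.6, colour = "grey20") +
    ggplot2::labs(
      title = sprintf("%s on %s (%s), s-score %.2f", object$query_id,
                      object$ref_id, object$orientation, object$s_score),
      x = "reference fragment", y = "query fragment"
    ) +
    ggplot2::theme_minimal()
}

#' Unitig overview of an assembly
#'
#' Unitig lengths in rank order, annotated with the color interval each
#' unitig spans (guided assemblies only).
#'
#' @param object An `assembly`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assembly <- function(object, ...) {
  u <- arrange(object$unitigs, dplyr::desc(.data$length)) |>
    mutate(rank = row_number())
  ggplot2::ggplot(u, ggplot2::aes(x = .data$rank, y = .data$length)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$start_color)) +
    ggplot2::scale_fill_viridis_c(na.value = "grey60") +
    ggplot2::labs(x = "unitig rank", y = "length (bp)", fill = "start color",
                  title = sprintf("%s assembly: %d unitigs",
                                  if (object$guided) "guided" else "unguided",
                                  nrow(u))) +
    ggplot2::theme_minimal()
}

#' Read colors against true genomic position
#'
#' For simulated data with known truth, plots each colored read's start
#' color against its true start coordinate; a guided coloring that preserves
#' genome order appears monotone within each chromosome.
#'
#' @param colored_reads Colored-read tibble.
#' @param truth Truth tibble from [simulate_reads()].
#' @return A ggplot object.
#' @export
plot_color_order <- function(colored_reads, truth) {
  df <- inner_join(colored_reads, truth, by = "read_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$start_color,
                                   colour = .data$chromosome)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "true start (bp)", y = "start color") +
    ggplot2::theme_minimal()
}
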