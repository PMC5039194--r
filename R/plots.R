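#' Plot projected rosette area over time
#'
#' Mean area per accession x treatment with standard-error ribbons,
#' the standard growth-curve panel of a salinity screen.
#'
#' @param areas Data frame with `accession`, `treatment`, `day`,
#'   `area_px`.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(areas) {
  summ <- areas |>
    dplyr::group_by(.data$accession, .data$treatment, .data$day) |>
    dplyr::summarise(mean = mean(.data$area_px, na.rm = TRUE),
                     se = sd(.data$area_px, na.rm = TRUE) /
                       sqrt(sum(is.finite(.data$area_px))),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$day, .data$mean,
                                     colour = .data$accession,
                                     linetype = .data$treatment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se,
                                      fill = .data$accession),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "days after salt treatment",
                  y = "projected rosette area (px)") +
    ggplot2::theme_minimal()
}

#' Plot hue abundance composition over time
#'
#' Stacked area chart of mean palette-hue fractions per day, one facet
#' per accession x treatment.
#'
#' @param hue A hue-abundance table (`accession`, `treatment`, `day`,
#'   `hue`, `fraction`).
#' @param palette Optional [build_hue_palette()] used to colour the
#'   bands with their actual RGB values.
#' @return A ggplot object.
#' @export
plot_hue_abundance <- function(hue, palette = NULL) {
  summ <- hue |>
    dplyr::filter(is.finite(.data$fraction)) |>
    dplyr::group_by(.data$accession, .data$treatment, .data$day, .data$hue) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(.data$day, .data$fraction,
                                          fill = factor(.data$hue))) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::facet_grid(accession ~ treatment) +
    ggplot2::labs(x = "days after salt treatment", y = "hue fraction",
                  fill = "hue") +
    ggplot2::theme_minimal()
  if (!is.null(palette)) {
    cols <- grDevices::rgb(palette$centroids[, 1], palette$centroids[, 2],
                           palette$centroids[, 3], maxColorValue = 255)
    p <- p + ggplot2::scale_fill_manual(values = cols)
  }
  p
}

#' Plot a chlorophyll-fluorescence trace
#'
#' Signal against time with annotated protocol windows highlighted.
#'
#' @param trace A trace tibble (`time_s`, `signal`, `event`).
#' @return A ggplot object.
#' @export
plot_chlf_trace <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(.data$time_s, .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = dplyr::filter(trace, .data$event != ""),
                        ggplot2::aes(colour = .data$event), size = 0.6) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)",
                  colour = "protocol event") +
    ggplot2::theme_minimal()
}

#' Plot SIIT per accession
#'
#' Mean SIIT1/SIIT2 with standard-error bars.
#'
#' @param siit_table A [siit()] result.
#' @return A ggplot object.
#' @export
plot_siit <- function(siit_table) {
  long <- siit_table |>
    tidyr::pivot_longer(dplyr::all_of(c("siit1", "siit2")),
                        names_to = "interval", values_to = "siit")
  summ <- long |>
    dplyr::group_by(.data$accession, .data$interval) |>
    dplyr::summarise(mean = mean(.data$siit, na.rm = TRUE),
                     se = sd(.data$siit, na.rm = TRUE) /
                       sqrt(sum(is.finite(.data$siit))),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$accession, .data$mean,
                                     fill = .data$interval)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "SIIT (GR salt / mean GR control)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a clustered accession x trait matrix
#'
#' @param x A `cluster_report` from [early_late_cluster_report()].
#' @param ... Unused.
#' @return A ggplot object (tile heatmap, rows and columns in
#'   dendrogram order).
#' @export
autoplot.cluster_report <- function(x, ...) {
  m <- x$matrix
  ro <- x$clustering$row_hclust$order
  co <- x$clustering$col_hclust$order
  df <- as.data.frame(as.table(m[ro, co, drop = FALSE]))
  names(df) <- c("accession", "trait", "z")
  df$accession <- factor(df$accession, levels = rownames(m)[ro])
  df$trait <- factor(df$trait, levels = colnames(m)[co])
  ggplot2::ggplot(df, ggplot2::aes(.data$trait, .data$accession,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
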