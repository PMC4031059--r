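# ggplot2 displays for the three result types: frequencies by step,
# frequencies by quartile, and percentile-interval sets.

epistasis_palette <- c(
  sign = "#D55E00", synergistic = "#0072B2",
  antagonistic = "#009E73", none = "#999999"
)

freq_long <- function(x) {
  tidyr::pivot_longer(
    tibble::as_tibble(x),
    dplyr::all_of(c("freq_sign", "freq_synergistic", "freq_antagonistic", "freq_none")),
    names_to = "class", values_to = "frequency", names_prefix = "freq_"
  )
}

#' Plot epistasis frequencies along the walk
#'
#' @param object A `step_freq` table from [epistasis_by_step()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.step_freq <- function(object, ...) {
  freq_long(object) %>%
    ggplot2::ggplot(ggplot2::aes(.data$step, .data$frequency, colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_walks), alpha = 0.7) +
    ggplot2::scale_colour_manual(values = epistasis_palette) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "walk step (window start)", y = "relative frequency",
                  colour = "epistasis", size = "walks") +
    ggplot2::theme_minimal()
}

#' Plot epistasis frequencies by fitness quartile
#'
#' @param object A `quartile_freq` table from [epistasis_by_quartile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.quartile_freq <- function(object, ...) {
  freq_long(object) %>%
    ggplot2::ggplot(ggplot2::aes(factor(.data$quartile), .data$frequency,
                                 fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = epistasis_palette) +
    ggplot2::labs(x = "fitness quartile of ab (1 = lowest)",
                  y = "relative frequency", fill = "epistasis") +
    ggplot2::theme_minimal()
}

#' Plot percentile intervals of quadruple fitnesses
#'
#' @param object An `interval_set` from [mean_regression_intervals()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interval_set <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$role, .data$median,
                               ymin = .data$`p2.5`, ymax = .data$`p97.5`,
                               colour = .data$role == "control")) +
    ggplot2::geom_pointrange(show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#0072B2", `FALSE` = "black")) +
    ggplot2::labs(x = NULL, y = "fitness",
                  subtitle = paste0(attr(object, "window") %||% "", " window")) +
    ggplot2::theme_minimal()
}
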