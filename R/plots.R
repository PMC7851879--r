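#' Plot incubation time series
#'
#' Concentration vs time, one panel per analyte, coloured by vessel,
#' with the least-squares trend whose slope becomes the flux/rate.
#'
#' @param data Long incubation tibble.
#' @return A ggplot object.
#' @export
plot_incubation <- function(data) {
  data <- validate_incubation(data)
  ggplot2::ggplot(data, ggplot2::aes(.data$time_h, .data$conc_uM,
                                     colour = .data$vessel_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$analyte), scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = expression(concentration~(mu*M)),
                  colour = "vessel")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an IPT denitrification panel
#'
#' Stacked components of total denitrification (water-nitrate-fuelled
#' `D_w` vs nitrification-coupled `D_n`) per vessel.
#'
#' @param object An `iptflux_denit_panel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iptflux_denit_panel <- function(object, ...) {
  long <- as_tibble(object) |>
    select("vessel_id", "D_w", "D_n") |>
    tidyr::pivot_longer(c("D_w", "D_n"), names_to = "component",
                        values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(.data$vessel_id, .data$rate,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "vessel", y = "denitrification (N-atom rate)",
                  fill = NULL)
}

#' Plot a nitrogen budget
#'
#' Areal rates per process, bare vs colonized, with the upscaled
#' holobiont contribution overlaid as points.
#'
#' @param budget An `iptflux_budget`.
#' @return A ggplot object.
#' @export
plot_budget <- function(budget) {
  long <- as_tibble(budget) |>
    select("process", "bare", "colonized") |>
    tidyr::pivot_longer(c("bare", "colonized"), names_to = "condition",
                        values_to = "rate") |>
    filter(is.finite(.data$rate))
  holo <- as_tibble(budget) |>
    filter(is.finite(.data$holobiont_contribution))
  ggplot2::ggplot(long, ggplot2::aes(.data$process, .data$rate,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(
      data = holo,
      ggplot2::aes(.data$process, .data$holobiont_contribution),
      inherit.aes = FALSE, shape = 23, fill = "white"
    ) +
    ggplot2::labs(x = NULL, y = expression(mu*mol~m^-2~h^-1), fill = NULL)
}

#' @export
tidy.iptflux_denit_panel <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(c("D15", "D14", "D_tot", "D_w", "D_n"),
                        names_to = "component", values_to = "rate")
}

#' @export
glance.iptflux_denit_panel <- function(x, ...) {
  tibble(
    n_vessels = nrow(x),
    mean_D_tot = mean(x$D_tot, na.rm = TRUE),
    mean_D_w = mean(x$D_w, na.rm = TRUE),
    mean_D_n = mean(x$D_n, na.rm = TRUE),
    prop_significant = mean(x$significant, na.rm = TRUE),
    epsilon = x$epsilon[[1]]
  )
}
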