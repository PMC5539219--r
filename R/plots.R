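#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result objects, plus
#' [plot_stratification()] for the horizon table.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name mobidom-plots
NULL

#' @rdname mobidom-plots
#' @exportS3Method
autoplot.mobility_fit <- function(object, ...) {
  counts <- object$pairs |>
    dplyr::count(.data$r_t, .data$r_t1)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$r_t, y = .data$r_t1)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(
      x = "rank R(t)", y = "rank R(t+1)", size = "individual-years",
      title = sprintf("R(t+1) = %.3f + %.3f R(t);  mobility rate 1 - b = %.3f",
                      object$intercept, object$slope, object$rate)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname mobidom-plots
#' @exportS3Method
autoplot.transition_counts <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(direction = factor(.data$direction,
                                     levels = c("up", "down", "same")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$direction,
                                  y = 100 * .data$proportion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "% of individual-year transitions") +
    ggplot2::theme_minimal()
}

#' @rdname mobidom-plots
#' @exportS3Method
autoplot.km_upward <- function(object, ...) {
  d <- tidy(object)
  # prepend the (0, 1) origin per stratum for a complete step curve
  origin <- d |> dplyr::distinct(.data$sex) |>
    dplyr::mutate(time = 0, estimate = 1)
  d <- dplyr::bind_rows(origin, dplyr::select(d, "sex", "time", "estimate")) |>
    dplyr::arrange(.data$sex, .data$time)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$estimate,
                                  colour = .data$sex)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "years since adulthood",
                  y = "P(no upward move yet)", colour = "sex") +
    ggplot2::theme_minimal()
}

#' @rdname mobidom-plots
#' @param table A [stratification_table()] tibble.
#' @export
plot_stratification <- function(table, ...) {
  check_columns(table, c("cohort", "horizon", "h_h", "l_l"), "table")
  d <- table |>
    tidyr::pivot_longer(c("h_h", "l_l"), names_to = "diagonal",
                        values_to = "probability") |>
    dplyr::mutate(diagonal = dplyr::recode(.data$diagonal,
                                           h_h = "H-H", l_l = "L-L"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$horizon, y = .data$probability,
                                  colour = .data$diagonal)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = sort(unique(d$horizon))) +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::labs(x = "horizon (years, log2 scale)",
                  y = "P(still in same stratum)", colour = NULL) +
    ggplot2::theme_minimal()
}
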