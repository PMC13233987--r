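#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot survival curves of the composite endpoint and its components
#'
#' @param object A curve table from [survival_curves()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cedesign_curves
#' @export
autoplot.cedesign_curves <- function(object, ...) {
  long <- tidyr_pivot_curves(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$survival,
                                     colour = .data$endpoint,
                                     linetype = factor(.data$arm))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "survival", colour = "endpoint",
                  linetype = "arm") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

tidyr_pivot_curves <- function(df) {
  base <- df[c("time", "arm")]
  dplyr::bind_rows(
    dplyr::mutate(base, endpoint = "component 1", survival = df$S_e1),
    dplyr::mutate(base, endpoint = "component 2", survival = df$S_e2),
    dplyr::mutate(base, endpoint = "composite", survival = df$S_ce)
  )
}

#' Plot a sensitivity scan
#'
#' Sample size (or ARE) as a function of the association, stratified by the
#' varied parameter.
#'
#' @param object A scan table from [sensitivity_tte()].
#' @param y Which column to draw: `"n_composite"` (default) or `"ARE"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cedesign_scan
#' @export
autoplot.cedesign_scan <- function(object, y = c("n_composite", "ARE"), ...) {
  y <- match.arg(y)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rho, y = .data[[y]],
                               colour = factor(.data$vary_value))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "association", y = y,
                  colour = unique(object$vary_name)) +
    ggplot2::theme_minimal()
}

#' Plot the time-varying hazard ratio of the composite endpoint
#'
#' @param design A [tte_design()].
#' @param n_points Grid resolution (defaults to the design's
#'   `subdivisions`).
#' @return A ggplot of `HR*(t)` over the follow-up.
#' @export
plot_hr_star <- function(design, n_points = NULL) {
  stopifnot(inherits(design, "tte_design"))
  n_points <- n_points %||% design$subdivisions
  tt <- seq(0, 1, length.out = n_points)
  df <- tibble::tibble(time = tt * design$followup_time,
                       hr = hr_star(design, tt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$hr)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "time", y = "HR*(t)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
#' @keywords internal
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a
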