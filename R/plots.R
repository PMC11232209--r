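#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_ribbon facet_wrap
#'   labs autoplot theme_minimal geom_hline
#' @export
ggplot2::autoplot

#' Plot joint-angle time series
#'
#' One panel per joint, coloured by side.
#'
#' @param angles Output of [extract_angle_series()].
#' @return A ggplot.
#' @export
plot_angle_series <- function(angles) {
  ggplot(angles, aes(x = .data$t, y = .data$angle, colour = .data$side)) +
    geom_line() +
    facet_wrap(~joint) +
    labs(x = "time (s)", y = "joint angle (deg)", colour = NULL) +
    theme_minimal()
}

#' Plot a template library's reference curves with tolerance bands
#'
#' @param library A [build_template()] result.
#' @param segment Segment name (default: first segment).
#' @return A ggplot.
#' @export
plot_template <- function(library, segment = library$timeline$name[1]) {
  cur <- library$curves |>
    filter(.data$segment == !!segment) |>
    mutate(u = (.data$g - 1) / max(.data$g - 1))
  ggplot(cur, aes(x = .data$u, y = .data$angle,
                  colour = .data$side, fill = .data$side)) +
    geom_ribbon(aes(ymin = .data$angle - .data$tolerance,
                    ymax = .data$angle + .data$tolerance),
                alpha = 0.15, colour = NA) +
    geom_line() +
    facet_wrap(~joint) +
    labs(title = segment, x = "normalized time", y = "reference angle (deg)") +
    theme_minimal()
}

#' @describeIn plot_angle_series autoplot method for session reports:
#'   per-segment accuracy bars.
#' @param object A `rehab_session_report`.
#' @param ... Unused.
#' @method autoplot rehab_session_report
#' @export
autoplot.rehab_session_report <- function(object, ...) {
  ggplot(object$segments, aes(x = .data$segment, y = .data$score)) +
    geom_col() +
    geom_hline(yintercept = object$overall, linetype = 2) +
    labs(x = NULL, y = "accuracy score (0-100)",
         subtitle = sprintf("overall %.1f (dashed)", object$overall)) +
    theme_minimal()
}

#' Power curve of the sample-size solver
#'
#' Power as a function of per-group n under a [power_spec()], with the
#' target power marked.
#'
#' @param spec A [power_spec()].
#' @param n_range Per-group sizes to plot (default 5:40).
#' @return A ggplot.
#' @export
plot_power_curve <- function(spec, n_range = 5:40) {
  df <- tibble(n = n_range,
               power = map_dbl(n_range, ~ power_rm_between(spec, .x * spec$k)))
  ggplot(df, aes(x = .data$n, y = .data$power)) +
    geom_line() +
    geom_hline(yintercept = spec$power, linetype = 2) +
    labs(x = "per-group n", y = "power") +
    theme_minimal()
}
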