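#' Along-tract profile plot with normative band
#'
#' One panel per parameter/hemisphere: the shaded healthy-control
#' normative band (2.5th-97.5th percentile interval), the control
#' median line, and individual patient profiles colored by group.
#'
#' @param profiles long profile tibble (subject_id, group, hemisphere,
#'   parameter, segment, median).
#' @param model a `normative_model`.
#' @param parameter,hemisphere which panel to draw.
#' @return a ggplot object.
#' @export
plot_profile <- function(profiles, model, parameter, hemisphere = "L") {
  band <- model$intervals |>
    dplyr::filter(.data$parameter == !!parameter, .data$hemisphere == !!hemisphere)
  pat <- profiles |>
    dplyr::filter(
      .data$parameter == !!parameter, .data$hemisphere == !!hemisphere,
      .data$group != "HC"
    )
  ggplot2::ggplot(band, ggplot2::aes(x = .data$segment)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$m), color = "steelblue3", linewidth = 0.9) +
    ggplot2::geom_line(
      data = pat,
      ggplot2::aes(
        y = .data$median, group = .data$subject_id,
        color = .data$group, linetype = .data$group
      )
    ) +
    ggplot2::scale_x_continuous(breaks = band$segment) +
    ggplot2::labs(
      x = "segment (frontal → temporal)",
      y = parameter,
      title = sprintf("%s, %s hemisphere", parameter, hemisphere)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_profile
#' @param object a `normative_model` (band only).
#' @param ... passed on; may include `profiles` to overlay patients.
#' @exportS3Method ggplot2::autoplot
autoplot.normative_model <- function(object, ...) {
  args <- list(...)
  profiles <- args$profiles %||%
    tibble(
      subject_id = character(), group = character(),
      hemisphere = character(), parameter = character(),
      segment = integer(), median = numeric()
    )
  first <- object$scale[1, ]
  plot_profile(profiles, object,
    parameter = first$parameter, hemisphere = first$hemisphere
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
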