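# ggplot2 graphics for fits, recovery reports and timecourses.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a promoter fit
#'
#' Observations with the model-predicted Blue curve (left) and the
#' inferred promoter activity (right facet).
#'
#' @param object A `promoter_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot promoter_fit
#' @export
autoplot.promoter_fit <- function(object, ...) {
  curve <- object$fitted_curve |>
    tidyr::pivot_longer(c("blue", "activity"), names_to = "panel",
                        values_to = "value") |>
    dplyr::mutate(panel = factor(.data$panel, c("blue", "activity"),
                                 c("Timer Blue (model vs data)",
                                   "inferred promoter activity g(t)")))
  obs <- dplyr::mutate(object$obs,
                       panel = factor("Timer Blue (model vs data)",
                                      levels(curve$panel)))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time_h,
                                      y = .data$value)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(y = .data$value),
                        color = "black", size = 2) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "time post-stimulation (h)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a recovery report
#'
#' True versus inferred promoter-activity curves per condition.
#'
#' @param object A `recovery_report` from [end_to_end_recovery()].
#' @param horizon Hours (default 72).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, horizon = 72, ...) {
  grid <- seq(0, horizon, by = 0.25)
  rescale <- object$max_raw / 100
  conds <- names(object$fits)
  df <- purrr::map(conds, function(cn) {
    tibble::tibble(condition = cn, time_h = grid,
                   activity = promoter_activity(
                     grid, object$fits[[cn]]$params) * rescale)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h,
                                   y = .data$activity,
                                   color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time post-stimulation (h)",
                  y = "inferred promoter activity (generator units/h)") +
    ggplot2::theme_minimal()
}

#' Timecourse summary plot
#'
#' Normalized MFI (or another summary column) against time, one line
#' per condition, faceted by channel.
#'
#' @param summaries Summary tibble from [summarize_events()].
#' @param value_col Column to plot (default `"mfi_normalized"`).
#' @return A ggplot.
#' @export
plot_timecourse <- function(summaries, value_col = "mfi_normalized") {
  stopifnot(value_col %in% names(summaries))
  aes <- ggplot2::aes(x = .data$time_h, y = .data[[value_col]])
  if ("condition" %in% names(summaries)) {
    aes$colour <- rlang::quo(.data$condition)
  }
  p <- ggplot2::ggplot(summaries, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "time post-stimulation (h)", y = value_col) +
    ggplot2::theme_minimal()
  if ("channel" %in% names(summaries)) {
    p <- p + ggplot2::facet_wrap(~channel, scales = "free_y")
  }
  p
}
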