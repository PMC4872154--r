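#' Plot methods
#'
#' `autoplot()` methods produce ggplot2 figures for the main result types:
#' accuracy-versus-depth curves, photobleaching composition, per-position
#' coverage/error profiles and detection scans.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name smflow-plots
NULL

#' @rdname smflow-plots
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$depth, y = 100 * .data$mean_identity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean coverage depth",
                  y = "consensus accuracy (%)") +
    ggplot2::theme_minimal()
}

#' @rdname smflow-plots
#' @export
autoplot.composition_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$label, y = 100 * .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "spots (%)") +
    ggplot2::theme_minimal()
}

#' @rdname smflow-plots
#' @export
autoplot.error_profile <- function(object, ...) {
  pp <- tidy(object) |>
    tidyr::pivot_longer(c("sub_rate", "del_rate"), names_to = "type",
                        values_to = "rate")
  ggplot2::ggplot(pp, ggplot2::aes(x = .data$pos, y = 100 * .data$rate,
                                   fill = .data$type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "reference position", y = "error rate (%)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname smflow-plots
#' @export
autoplot.consensus_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$pos, y = .data$coverage)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "reference position", y = "coverage") +
    ggplot2::theme_minimal()
}

#' @rdname smflow-plots
#' @export
autoplot.detection_scan <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = 100 * .data$fraction,
                               y = 100 * .data$pooled_frequency)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "true mutant fraction (%)",
                  y = "measured mutant frequency (%)") +
    ggplot2::theme_minimal()
}
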