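# ggplot2 displays: capacitance heat map, fit-vs-measured, fleet CVRMSE.

#' @export
autoplot.capacitance_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$channel, y = .data$time_h,
                               fill = .data$value_norm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 1), name = "normalized") +
    ggplot2::facet_wrap(ggplot2::vars(.data$run_id)) +
    ggplot2::labs(x = NULL, y = "time (h)",
                  title = "Capacitance map (per-channel min-max over all runs)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot estimated versus measured VCC for one run
#'
#' Dense line: the model estimate on the online grid; points: offline
#' measured VCC.
#'
#' @param model Any fitted estimator accepted by [predict_vcc()].
#' @param run A [fermentation_run()].
#' @return A ggplot object.
#' @export
plot_fit <- function(model, run) {
  est <- predict_vcc(model, run)
  ggplot2::ggplot() +
    ggplot2::geom_line(data = est,
                       ggplot2::aes(x = .data$time_h, y = .data$vcc_est),
                       color = "steelblue") +
    ggplot2::geom_point(data = run$offline,
                        ggplot2::aes(x = .data$time_h,
                                     y = .data$vcc_1e5_per_ml)) +
    ggplot2::labs(x = "time (h)", y = "VCC (1e5 cells/mL)",
                  title = sprintf("%s: estimated (line) vs measured (points)",
                                  run$run_id)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.transfer_experiment <- function(object, ...) {
  ggplot2::ggplot(object$reports,
                  ggplot2::aes(x = .data$run_id, y = .data$cvrmse_whole,
                               fill = .data$verdict)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 33, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "whole-process CVRMSE (%)",
                  title = "Transferred model performance (dashed: 33% limit)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
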