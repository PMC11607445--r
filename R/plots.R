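# autoplot methods for the result objects (ggplot2)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a forecast-error grid as a heatmap
#'
#' @param object An [mse_grid()] result.
#' @param max_mse Cap for the fill scale (variance units).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mse_grid
#' @export
autoplot.mse_grid <- function(object, max_mse = 1.5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$obs_time_h, .data$horizon_h,
                                       fill = pmin(.data$mse, max_mse))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MSE\n(variance units)", na.value = "grey90") +
    ggplot2::labs(x = "observation time (h)", y = "forecast horizon (h)",
                  title = paste0("Forecast error: ", attr(object, "variable"))) +
    ggplot2::theme_minimal()
}

#' Plot side-effect contrast densities over time
#'
#' @param object An [side_effect_contrast()] result.
#' @param at_hours Hours at which densities are drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abx_contrast
#' @export
autoplot.abx_contrast <- function(object, at_hours = c(12, 24, 48, 72), ...) {
  pair <- attr(object, "abx_pair")
  df <- dplyr::filter(object, .data$time_h %in% at_hours)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta, colour = factor(.data$time_h))) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~outcome, scales = "free") +
    ggplot2::labs(x = sprintf("Δ (%s − %s)", pair[1], pair[2]),
                  colour = "hours after\ntreatment start") +
    ggplot2::theme_minimal()
}

#' Plot matched-pair SOFA discrepancy curves
#'
#' @param object A [counterfactual_matching()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abx_matching
#' @export
autoplot.abx_matching <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_h, .data$mean_abs_diff,
                                       colour = .data$arm, fill = .data$arm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hours after onset", y = "mean |Δ SOFA| of matched pairs") +
    ggplot2::theme_minimal()
}

#' Plot the average treatment-improvement curve
#'
#' @param object An [average_treatment_improvement()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abx_improvement
#' @export
autoplot.abx_improvement <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$time_h, .data$mean_delta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "hours after first treatment",
                  y = "Δ SOFA (optimal − factual)") +
    ggplot2::theme_minimal()
}

#' Plot a decision record: per-option forecast SOFA with warnings
#'
#' @param object A [select_optimal()] record (one decision time).
#' @param patient Patient to display (default: first).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot abx_decision
#' @export
autoplot.abx_decision <- function(object, patient = NULL, ...) {
  patient <- patient %||% object$patient_id[1L]
  df <- dplyr::filter(object, .data$patient_id == patient)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$option, .data$sofa_pred_end),
                                   .data$sofa_pred_end, fill = .data$warned)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$selected),
                        ggplot2::aes(y = .data$sofa_pred_end + 0.3),
                        shape = 8, size = 3, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue", `TRUE` = "firebrick")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("forecast SOFA at +%d h", df$horizon_h[1L]),
                  title = paste0(patient, " @ ", df$decision_time_h[1L], " h"),
                  fill = "warned") +
    ggplot2::theme_minimal()
}
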