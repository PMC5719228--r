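#' Plot a horizon sweep
#'
#' auROC (with the DeLong 95% interval as a ribbon) against the prediction
#' horizon.
#'
#' @param x a `ward_sweep` tibble from [horizon_sweep()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ward_sweep <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$horizon_eval, y = .data$auroc)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::labs(x = "Prediction horizon (hours)", y = "auROC") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ward_sweep
#' @export
plot_horizon_sweep <- function(x, ...) autoplot.ward_sweep(x, ...)

#' Plot a cross-horizon auROC grid as a heatmap
#'
#' @param x a `ward_grid` tibble from [cross_horizon()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ward_grid <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$horizon_eval,
                                  y = .data$horizon_train,
                                  fill = .data$auroc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0.5, 1), oob = scales_squish) +
    ggplot2::labs(x = "Evaluation horizon (hours)",
                  y = "Training horizon (hours)", fill = "auROC") +
    ggplot2::theme_minimal()
}

# minimal squish so we do not depend on scales directly
scales_squish <- function(x, range = c(0, 1), ...) clamp(x, range[1], range[2])

#' @rdname autoplot.ward_grid
#' @export
plot_cross_horizon <- function(x, ...) autoplot.ward_grid(x, ...)

#' Plot an empirical ROC curve
#'
#' @param scores_cases,scores_controls numeric score vectors.
#' @return a ggplot of sensitivity against 1 - specificity.
#' @export
plot_roc_curve <- function(scores_cases, scores_controls) {
  thr <- sort(unique(c(-Inf, scores_cases, scores_controls, Inf)),
              decreasing = TRUE)
  df <- tibble::tibble(
    fpr = vapply(thr, function(t) mean(scores_controls >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores_cases >= t), numeric(1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}
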