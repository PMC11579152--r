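#' Box plot of AIC across candidate state counts
#'
#' One point per fitted series, boxed by `M`, mirroring the comparison used
#' to settle on four states.
#'
#' @param profile Output of [aic_profile()].
#' @return A ggplot object.
#' @export
plot_aic_profile <- function(profile) {
  ggplot2::ggplot(dplyr::filter(profile, !is.na(.data$aic)),
                  ggplot2::aes(factor(.data$M), .data$aic)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Number of hidden states M", y = "AIC") +
    ggplot2::theme_minimal()
}

#' Bar chart of LOOCV AUROC per classifier
#'
#' @param report The `report` tibble of [run_pipeline()] (or any tibble
#'   with `classifier`, `auroc`, `trial`, `dataset`).
#' @return A ggplot object.
#' @export
plot_auroc <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(.data$classifier, .data$auroc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::facet_grid(dataset ~ trial, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "LOOCV AUROC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Arena view of trajectories
#'
#' @param coords A `trajectory_df`.
#' @param arena_radius Arena radius for the outline (Vm).
#' @return A ggplot object faceted by trial, coloured by group.
#' @export
plot_trajectories <- function(coords, arena_radius = 37.5) {
  circ <- tibble(a = seq(0, 2 * pi, length.out = 200))
  ggplot2::ggplot(coords, ggplot2::aes(.data$x, .data$y,
                                       group = .data$subject,
                                       colour = .data$group)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = arena_radius * cos(.data$a),
                                    y = arena_radius * sin(.data$a)),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::facet_wrap(~trial, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Vm)", y = "y (Vm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn loocv_evaluate ROC curve of a LOOCV evaluation.
#' @param object A `loocv_eval` object.
#' @param ... Unused.
#' @export
autoplot.loocv_eval <- function(object, ...) {
  pts <- roc_points(object$scores$score, object$scores$label)
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s: AUROC = %.3f", object$classifier, object$auroc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
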