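#' Plot a norm profile
#'
#' Shows the per-bin proportion of participants marking an event boundary,
#' one panel per video.
#'
#' @param norms Output of [compute_norms()].
#' @param videos Optional character vector restricting the panels.
#' @return A ggplot object.
#' @export
plot_norms <- function(norms, videos = NULL) {
  if (!is.null(videos)) norms <- norms[norms$video_id %in% videos, ]
  ggplot2::ggplot(norms, ggplot2::aes(x = .data$bin_index, y = .data$proportion)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::facet_wrap(~video_id, scales = "free_x") +
    ggplot2::labs(x = "Time bin (s)", y = "Proportion marking a boundary",
                  title = "Segmentation norm profiles") +
    ggplot2::theme_minimal()
}

#' Plot agreement score distributions by group and condition
#'
#' @param agreement Agreement table from [score_agreement()].
#' @param subjects Subject table with `subject_id` and `group`.
#' @return A ggplot object.
#' @export
plot_agreement <- function(agreement, subjects) {
  d <- dplyr::left_join(agreement,
                        dplyr::select(subjects, "subject_id", "group"),
                        by = "subject_id")
  d <- d[!is.na(d$scaled), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$scaled,
                                  fill = .data$condition)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Scaled segmentation agreement",
                  fill = "Narrative") +
    ggplot2::theme_minimal()
}

#' Effect plot for a mediation result
#'
#' Point estimates and 95% Monte-Carlo intervals for the indirect (ACME),
#' direct (ADE) and total effects.
#'
#' @param object A `mediation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$term != "prop_mediated", ]
  d$term <- factor(toupper(d$term), levels = c("TOTAL", "ADE", "ACME"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(
      x = sprintf("Effect of %s on recall proportion", object$predictor),
      y = NULL,
      title = sprintf("Mediation through segmentation agreement (%.0f%% mediated)",
                      100 * object$prop_mediated)) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a crossed mixed-model fit
#'
#' @param object A `mem_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mem_fit
#' @export
autoplot.mem_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$term != "(Intercept)", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std_error,
                                          xmax = .data$estimate + 1.96 * .data$std_error)) +
    ggplot2::labs(x = sprintf("Fixed effect on %s", object$outcome), y = NULL) +
    ggplot2::theme_minimal()
}
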