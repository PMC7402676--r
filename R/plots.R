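# ggplot2 displays for the main result types. These mirror the standard
# figures of mixture meta-analyses: forest plots of subgroup effects,
# effect trajectories over decomposition stage, and moderator scatter
# plots.

#' Forest plot of a subgroup meta-analysis
#'
#' @param object A `litter_subgroup`.
#' @param percent Plot on the percent-effect scale instead of lnRR.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.litter_subgroup <- function(object, percent = FALSE, ...) {
  d <- object$groups
  if (percent) {
    d <- d |>
      dplyr::mutate(est = .data$percent_effect,
                    lo = percent_effect(.data$ci_low),
                    hi = percent_effect(.data$ci_high))
    xlab <- "Mixture effect (%)"
  } else {
    d <- d |>
      dplyr::mutate(est = .data$pooled_lnrr, lo = .data$ci_low,
                    hi = .data$ci_high)
    xlab <- "Effect size (lnRR)"
  }
  d$label <- sprintf("%s (%d)", d$group, d$k)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$est, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi), height = 0.15,
      na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$low_n), size = 2.5,
                        na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = xlab, y = NULL,
                  title = sprintf("Mixture effects by %s", object$by)) +
    ggplot2::theme_minimal()
}

#' Effect trajectory across decomposition stages
#'
#' @param object A `litter_staging` table from [staged_meta()].
#' @param ... Unused.
#' @return A ggplot of pooled lnRR with bootstrap CIs per mass-loss
#'   interval.
#' @export
autoplot.litter_staging <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(.data$k > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$interval,
                                  y = .data$pooled_lnrr, group = 1)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.15, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$low_n), size = 2.5,
                        na.rm = TRUE) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "Expected (additive-null) mass loss interval (%)",
                  y = "Effect size (lnRR)",
                  title = sprintf("Mixture effect by decomposition stage (%s)",
                                  attr(object, "response"))) +
    ggplot2::theme_minimal()
}

#' Scatter plot of mixture effects against a moderator
#'
#' @param x Moderator values.
#' @param y Effect sizes (lnRR).
#' @param xlab Axis label for the moderator.
#' @return A ggplot with the OLS fit line and its r-squared / p annotation.
#' @export
plot_moderator <- function(x, y, xlab = "Moderator") {
  fit <- moderator_regression(x, y)
  d <- tibble::tibble(x = x, y = y)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black", linewidth = 0.6, na.rm = TRUE) +
    ggplot2::annotate(
      "text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
      label = sprintf("r^2 == %.3f~(p == %.3g)", fit$r_squared,
                      fit$p_value),
      parse = TRUE) +
    ggplot2::labs(x = xlab, y = "Effect size (lnRR)") +
    ggplot2::theme_minimal()
}
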