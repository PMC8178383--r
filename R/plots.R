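#' Plot a meta-analysis: QTL peaks and MQTL intervals per chromosome
#'
#' Projected QTL peaks are drawn as points (with their 95% CI as thin
#' ranges) and the derived MQTL CIs as thick segments underneath.
#'
#' @param object a `meta_analysis`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot meta_analysis
#' @export
autoplot.meta_analysis <- function(object, ...) {
  chrom_col <- if ("chromosome_cons" %in% names(object$projected))
    "chromosome_cons" else "chromosome"
  qtl <- mutate(object$projected, chromosome = .data[[chrom_col]])
  ggplot2::ggplot(qtl, ggplot2::aes(x = .data$peak_cons)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_left, xmax = .data$ci_right, y = 1.1),
      height = 0, linewidth = 0.2, alpha = 0.4,
      position = ggplot2::position_jitter(height = 0.35, width = 0)) +
    ggplot2::geom_point(ggplot2::aes(y = 1.1), size = 0.8, alpha = 0.6) +
    ggplot2::geom_segment(
      data = object$mqtl,
      ggplot2::aes(x = .data$ci_left, xend = .data$ci_right,
                   y = 0.4, yend = 0.4),
      linewidth = 3, colour = "firebrick", inherit.aes = FALSE) +
    ggplot2::facet_wrap(~chromosome, ncol = 1, strip.position = "right") +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(0, 2)) +
    ggplot2::labs(x = "consensus position (cM)",
                  title = "Projected QTL and meta-QTL") +
    ggplot2::theme_minimal()
}

#' Model-selection profile: criterion values against k
#'
#' @param x a `meta_analysis`.
#' @return a ggplot object, one panel per chromosome, the chosen k marked.
#' @export
plot_model_selection <- function(x) {
  df <- model_selection_report(x) |>
    tidyr::pivot_longer(c("aic", "aicc", "bic", "awe"),
                        names_to = "criterion", values_to = "value") |>
    filter(is.finite(.data$value))
  chosen <- model_selection_report(x) |> filter(.data$chosen)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$value,
                                   colour = .data$criterion)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(data = chosen,
                        ggplot2::aes(xintercept = .data$k),
                        linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~chromosome, scales = "free_y") +
    ggplot2::labs(y = "criterion value",
                  title = "Mixture model choice per chromosome") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
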