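# ggplot2 visualizations of PWMs, SDR score profiles and mutation
# enrichment.

#' Heatmap of a kinase specificity PWM
#'
#' @param object A `kinase_pwm`.
#' @param ... Unused.
#' @return A ggplot object (residue x substrate position, fill =
#'   frequency).
#' @method autoplot kinase_pwm
#' @export
autoplot.kinase_pwm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$position, levels = WINDOW_POSITIONS),
    y = factor(.data$residue, levels = rev(AMINO_ACIDS)),
    fill = .data$frequency
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(
      title = sprintf("Specificity model: %s", object$kinase_id),
      x = "substrate position", y = NULL, fill = "frequency"
    ) +
    ggplot2::theme_minimal()
}

#' Per-column SDR score profiles for the three scorers
#'
#' @param object An `sdr_result`.
#' @param ... Unused.
#' @return A ggplot object with one facet per scoring method and SDR
#'   calls highlighted.
#' @method autoplot sdr_result
#' @export
autoplot.sdr_result <- function(object, ...) {
  df <- object$table |>
    tidyr::pivot_longer(c("groupsim", "relief", "speer"),
                        names_to = "method", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$score)) +
    ggplot2::geom_line(color = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$is_sdr),
      color = "firebrick", size = 1.5
    ) +
    ggplot2::facet_wrap(~method, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      title = sprintf("SDR ensemble (top-%d intersection, %d call%s)",
                      object$k, length(object$sdr_columns),
                      if (length(object$sdr_columns) == 1) "" else "s"),
      x = "alignment column", y = "score"
    ) +
    ggplot2::theme_minimal()
}

#' Per-site mutation fractions by functional category
#'
#' @param object A `mutation_enrichment`.
#' @param ... Unused.
#' @return A ggplot boxplot of per-site mean mutation fractions per
#'   category.
#' @method autoplot mutation_enrichment
#' @export
autoplot.mutation_enrichment <- function(object, ...) {
  ggplot2::ggplot(object$site_means, ggplot2::aes(
    x = .data$category, y = .data$mean_fraction, fill = .data$category
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::labs(
      x = NULL,
      y = "mean per-kinase mutation fraction per site"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of per-site mutation frequency for two specificity classes
#'
#' @param contrast Output of [specificity_contrast()].
#' @param spec_a,spec_b Axis labels for the two classes.
#' @return A ggplot object with SDR sites highlighted.
#' @export
plot_specificity_contrast <- function(contrast, spec_a = "class A",
                                      spec_b = "class B") {
  ggplot2::ggplot(contrast, ggplot2::aes(
    x = .data$mean_a, y = .data$mean_b, color = .data$is_sdr
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey70") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "firebrick"),
                                labels = c("other", "SDR"), name = NULL) +
    ggplot2::labs(x = sprintf("mutation frequency (%s kinases)", spec_a),
                  y = sprintf("mutation frequency (%s kinases)", spec_b)) +
    ggplot2::theme_minimal()
}
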