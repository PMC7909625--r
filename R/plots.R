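#' Forest plot of an analysis report
#'
#' Draws the observational-versus-MR contrast: one horizontal CI per estimate
#' in [forest_table()], faceted by exposure form, with a dashed null line.
#'
#' @param object An `mr_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_report <- function(object, ...) {
  ft <- forest_table(object)
  ggplot2::ggplot(ft, ggplot2::aes(x = .data$estimate, y = .data$label,
                                   colour = .data$analysis)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$exposure), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(
      x = expression("Effect on young-adult BMI (kg/" * m^2 * " per unit exposure)"),
      y = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of per-SNP summary associations
#'
#' Outcome association against exposure association per SNP (oriented so
#' exposure associations are non-negative), with the IVW line through the
#' origin and the MR-Egger line. A non-zero Egger intercept is the visual
#' signature of directional pleiotropy.
#'
#' @param object A `snp_summaries` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snp_summaries <- function(object, ...) {
  flip <- sign(object$beta_exposure)
  flip[flip == 0] <- 1
  df <- dplyr::mutate(object,
                      bx = .data$beta_exposure * flip,
                      by = .data$beta_outcome * flip)
  ivw <- mr_ivw(object)$estimates$estimate
  egg <- mr_egger(object)$estimates
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$se_outcome,
                                        ymax = .data$by + .data$se_outcome),
                           width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - .data$se_exposure,
                                         xmax = .data$bx + .data$se_exposure),
                            height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = ivw, intercept = 0, colour = "steelblue") +
    ggplot2::geom_abline(slope = egg$estimate[egg$term == "slope"],
                         intercept = egg$estimate[egg$term == "intercept"],
                         colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = "SNP effect on exposure (per allele)",
                  y = "SNP effect on outcome (per allele)") +
    ggplot2::theme_minimal()
}

#' Plot a birth-year reference population
#'
#' Mean AAM (with +/- 1 SD ribbon) and the early-menarche proportion across
#' birth years, the two quantities the segmentation and standardization run
#' on.
#'
#' @param ref Reference table.
#' @param partition Optional partition whose boundaries are drawn as vertical
#'   lines.
#' @return A ggplot object.
#' @export
plot_reference <- function(ref, partition = NULL) {
  p <- ggplot2::ggplot(ref, ggplot2::aes(x = .data$birth_year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_aam - .data$sd_aam,
                                      ymax = .data$mean_aam + .data$sd_aam),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_aam)) +
    ggplot2::geom_line(ggplot2::aes(y = 10 + 10 * .data$prop_early),
                       colour = "firebrick") +
    ggplot2::scale_y_continuous(
      name = "Mean AAM (years)",
      sec.axis = ggplot2::sec_axis(~ (. - 10) / 10,
                                   name = "Proportion AAM < 14")
    ) +
    ggplot2::labs(x = "Birth year") +
    ggplot2::theme_minimal()
  if (!is.null(partition) && nrow(partition) > 1) {
    p <- p + ggplot2::geom_vline(xintercept = partition$start_year[-1] - 0.5,
                                 linetype = "dotted")
  }
  p
}
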