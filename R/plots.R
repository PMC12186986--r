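#' Forest-style plot of trait-adjusted SNP effects
#'
#' For one variant, plots the step-2 SNP effect on ln(eGFRcrea) under
#' adjustment for each trait in turn, with 95% confidence intervals;
#' stringent-Tukey outliers are highlighted. Requires ggplot2.
#'
#' @param screen data.frame from [mediation_screen()].
#' @param rsid variant to display (default: first in `screen`).
#' @return a ggplot object.
#' @export
plot_mediation_forest <- function(screen, rsid = screen$rsid[1]) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  d <- screen[screen$rsid == rsid, , drop = FALSE]
  d$trait_name <- stats::reorder(d$trait_name, d$b2)
  ggplot2::ggplot(d, ggplot2::aes(x = b2, y = trait_name,
                                  color = outlier_flag)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = d$b1[1], linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = b2 - 1.96 * se2,
                                          xmax = b2 + 1.96 * se2),
                             linewidth = 0.3, size = 0.3) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "red"),
                                name = "outlier") +
    ggplot2::labs(x = "trait-adjusted SNP effect on ln(eGFRcrea)",
                  y = NULL, title = rsid) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Interaction plot: predicted ln(eGFRcrea) versus dosage by TSH stratum
#'
#' Displays the fitted outcome-dosage lines at TSH one SD below, at, and
#' one SD above the mean, with 95% confidence ribbons. Requires ggplot2.
#'
#' @param pred data.frame from [predict_at_tsh_levels()].
#' @return a ggplot object.
#' @export
plot_interaction_tsh <- function(pred) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  pred$tsh_level <- factor(pred$tsh_level,
                           levels = c("low", "average", "high"))
  ggplot2::ggplot(pred, ggplot2::aes(x = dosage, y = fit,
                                     color = tsh_level,
                                     fill = tsh_level)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lwr, ymax = upr),
                         alpha = 0.15, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "allelic dosage", y = "predicted ln(eGFRcrea)",
                  color = "TSH", fill = "TSH") +
    ggplot2::theme_minimal(base_size = 10)
}

utils::globalVariables(c("b2", "trait_name", "outlier_flag", "se2",
                         "dosage", "lwr", "upr", "tsh_level"))
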