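#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_boxplot
#'   geom_smooth labs facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot PCA scores of a genotype set
#'
#' @param object An [str_pca()] object.
#' @param axes Which two PCs to plot.
#' @param colour Metadata column mapped to colour ("category" or "variety").
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.str_pca <- function(object, axes = c(1, 2), colour = "category",
                             ...) {
  ve <- round(100 * object$variance_explained[axes], 1)
  ggplot(object$scores,
         aes(x = .data[[paste0("PC", axes[1])]],
             y = .data[[paste0("PC", axes[2])]],
             colour = if (colour %in% names(object$scores))
               .data[[colour]] else NULL)) +
    geom_point(alpha = 0.8) +
    labs(x = sprintf("PC%d (%.1f%%)", axes[1], ve[1]),
         y = sprintf("PC%d (%.1f%%)", axes[2], ve[2]),
         colour = colour) +
    theme_minimal()
}

#' Allele-specific stutter-ratio trend plot
#'
#' Mean stutter ratio per parent allele against repeat number, per marker
#' and stutter type.
#'
#' @param stats A [stutter_stats()] result.
#' @param type Stutter type to show (default backward, "n-k").
#' @return A ggplot.
#' @export
plot_stutter_trend <- function(stats, type = "n-k") {
  d <- filter(stats$by_allele, .data$type == !!type, !is.na(.data$parent_nr))
  ggplot(d, aes(x = .data$parent_nr, y = .data$mean_sr)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linewidth = 0.4, colour = "grey40") +
    facet_wrap(~marker, scales = "free") +
    labs(x = "parent allele repeat number",
         y = "mean stutter ratio S_R",
         title = sprintf("Allele-specific %s stutter", type)) +
    theme_minimal()
}

#' Heterozygote balance against DNA amount
#'
#' @param het_by_dose A [het_balance()] result carrying a `dose_group`
#'   column (e.g. joined from a dilution series).
#' @return A ggplot of Hb' distributions per dose.
#' @export
plot_het_balance <- function(het_by_dose) {
  stopifnot("dose_group" %in% names(het_by_dose))
  ggplot(het_by_dose,
         aes(x = factor(.data$dose_group), y = .data$hb_prime)) +
    geom_boxplot() +
    labs(x = "DNA per reaction (ng)", y = "Hb' (smaller / larger)") +
    theme_minimal()
}
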