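#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a genotype-methylation fit
#'
#' Scatter of methylation against alternate-allele dosage with the fitted
#' line and the extrapolated per-genotype means.
#'
#' @param object A [fit_cpg_snp()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpg_snp_fit
#' @export
autoplot.cpg_snp_fit <- function(object, ...) {
  means <- tibble(dosage = 0:2, meth = as.numeric(object$fitted_means))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dosage, y = .data$meth)) +
    ggplot2::geom_jitter(width = 0.05, height = 0, alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::geom_point(data = means, colour = "firebrick", size = 3,
                        shape = 18) +
    ggplot2::scale_x_continuous(breaks = 0:2) +
    ggplot2::labs(
      x = "alternate-allele dosage", y = "methylation rate",
      title = sprintf("r = %.2f, p = %.2g, accuracy = %.2f",
                      object$r, object$p_value, object$accuracy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot forward-minus-reverse strand methylation differences by group
#'
#' The strand-asymmetry view of CpG-disrupting variants: C/C homozygotes
#' cluster at zero difference while C/A and C/G heterozygotes sit near +0.5.
#'
#' @param asymmetry Output of [strand_asymmetry()].
#' @param group Name of the grouping column (default `"genotype"`).
#' @return A ggplot.
#' @export
plot_strand_asymmetry <- function(asymmetry, group = "genotype") {
  ggplot2::ggplot(
    asymmetry[!is.na(asymmetry$difference), ],
    ggplot2::aes(x = .data[[group]], y = .data$difference,
                 fill = .data[[group]])
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "forward - reverse methylation rate") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot pairwise correlation densities by relationship group
#'
#' @param object A [pairwise_sample_correlation()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pairwise_correlation
#' @export
autoplot.pairwise_correlation <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$r, colour = .data$relationship)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "pairwise correlation", y = "density",
                  colour = "relationship") +
    ggplot2::theme_minimal()
}

#' Plot SNP overlap fractions of differential methylation by pair type
#'
#' @param audits Row-bound [audit_pair()] results.
#' @return A ggplot.
#' @export
plot_pair_audit <- function(audits) {
  ggplot2::ggplot(
    audits[!is.na(audits$fraction_overlap), ],
    ggplot2::aes(x = .data$pair_type, y = .data$fraction_overlap,
                 fill = .data$pair_type)
  ) +
    ggplot2::geom_boxplot(alpha = 0.7) +
    ggplot2::labs(x = NULL,
                  y = "fraction of differential CpGs overlapping a variant") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
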