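#' Plot helpers for selection results
#'
#' @name plots
NULL

#' Forest-style plot of gene-level selection
#'
#' @param results selection-result tibble (e.g. `tidy()` of an `omega_fit`)
#' @return a ggplot
#' @export
plot_gene_selection <- function(results) {
  df <- dplyr::filter(results, is.finite(.data$dnds))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dnds, y = .data$gene,
                                   colour = .data$mclass)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dN/dS (observed / expected)", y = NULL,
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Needle plot of per-residue selection scores
#'
#' @param scores output of [site_selection()] with `unit = "residue"`
#' @param q_threshold residues at q below this are highlighted
#' @return a ggplot
#' @export
plot_site_selection <- function(scores, q_threshold = 0.1) {
  df <- scores |>
    dplyr::mutate(residue = as.numeric(.data$unit_id),
                  significant = .data$q_value < q_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$score)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$residue, yend = 0,
                                       colour = .data$significant)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "protein position", y = "selection score (log2 obs/exp)",
                  title = unique(df$gene)) +
    ggplot2::theme_minimal()
}

#' Effect-size plot of covariate associations
#'
#' @param x an `association_fit`
#' @param ... unused
#' @return a ggplot
#' @method autoplot association_fit
#' @export
autoplot.association_fit <- function(x, ...) {
  df <- dplyr::filter(x$results, .data$converged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$term,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~response, scales = "free_x") +
    ggplot2::labs(x = "effect size", y = NULL) +
    ggplot2::theme_minimal()
}
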