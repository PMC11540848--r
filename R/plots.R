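# ggplot2 views of the main result types.

#' Plot a QTL scan: effect size against minor allele frequency
#'
#' Significant traits (q below the cutoff when a `qvalue` column is
#' present, otherwise all) are drawn with `|beta|` against the top
#' variant's MAF; lower-frequency alleles are expected to carry larger
#' effects.
#'
#' @param object A `qtl_scan` tibble (see [map_qtl()]); needs `maf` joined
#'   from the variant metadata or present via [nominal_scan()] records.
#' @param geno Optional [geno_matrix()] to look up the top variants' MAF.
#' @param q_cutoff Significance cutoff when `qvalue` is present.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qtl_scan <- function(object, geno = NULL, q_cutoff = 0.05, ...) {
  df <- tibble::as_tibble(object)
  if (!("maf" %in% names(df)) && !is.null(geno)) {
    df$maf <- geno$variants$maf[match(df$variant_id, geno$variants$variant_id)]
  }
  if ("qvalue" %in% names(df)) {
    df <- df[!is.na(df$qvalue) & df$qvalue < q_cutoff, ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$maf, y = abs(.data$beta))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "minor allele frequency", y = "|effect size|",
                  title = "Significant QTLs: effect size vs MAF") +
    ggplot2::theme_minimal()
}

#' Plot colocalization posteriors
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of PP0..PP4.
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "posterior probability",
                  title = "Colocalization posteriors") +
    ggplot2::theme_minimal()
}

#' Plot SMR results as a forest plot
#'
#' @param object An `smr_result` tibble from [run_smr()].
#' @param ... Unused.
#' @return A ggplot forest plot of `b_xy` with 95% confidence intervals.
#' @export
autoplot.smr_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b_xy, y = .data$trait_id,
                                   colour = .data$verdict)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$b_xy - 1.96 * .data$se_xy,
      xmax = .data$b_xy + 1.96 * .data$se_xy
    ), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "effect of exposure on outcome (b_xy)", y = NULL,
                  title = "SMR effect estimates") +
    ggplot2::theme_minimal()
}

#' Conditional-vs-unconditional significance plot for mediation results
#'
#' Each point is a protein trait; the diagonal marks no attenuation, and
#' transcript-dependent traits fall far below it.
#'
#' @param results Output of [mediation_classify()].
#' @return A ggplot object.
#' @export
plot_mediation <- function(results) {
  df <- tibble::as_tibble(results)
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$unconditional_p), y = -log10(.data$conditional_p),
    colour = .data$classification
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10 p (pQTL)", y = "-log10 p (pQTL | mRNA)",
                  title = "pQTL significance before and after conditioning on mRNA") +
    ggplot2::theme_minimal()
}

#' Scree plot of a factor fit
#'
#' @param fit A `factor_fit` from [estimate_factors()].
#' @param n_show Number of components to display.
#' @return A ggplot object.
#' @export
plot_factor_variance <- function(fit, n_show = 20L) {
  ve <- fit$var_explained[seq_len(min(n_show, length(fit$var_explained)))]
  df <- tibble::tibble(component = seq_along(ve), var_explained = ve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$var_explained)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_vline(xintercept = fit$k + 0.5, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "principal component", y = "variance explained",
                  title = sprintf("Hidden-factor scree (K = %d)", fit$k)) +
    ggplot2::theme_minimal()
}
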