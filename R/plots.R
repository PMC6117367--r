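#' Scatter plot of a phenome-wide association scan
#'
#' One point per phenotype at -log10(p), colored by selection status
#' (Bonferroni, FDR, neither), the standard way a phenome scan for a single
#' predicted biomarker is summarized.
#'
#' @param results Annotated results tibble (with `q` and significance
#'   flags from [adjust_multiplicity()]; plain [run_phewas()] output is
#'   also accepted).
#' @param bonferroni_threshold Optional threshold line.
#' @return A ggplot object.
#' @export
plot_phewas <- function(results, bonferroni_threshold = NULL) {
  df <- dplyr::filter(results, .data$converged, !is.na(.data$p))
  df$selection <- "not selected"
  if ("fdr_significant" %in% names(df)) {
    df$selection[df$fdr_significant] <- "FDR"
  }
  if ("bonferroni_significant" %in% names(df)) {
    df$selection[df$bonferroni_significant] <- "Bonferroni"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$phecode, y = -log10(.data$p), color = .data$selection)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(values = c(
      "Bonferroni" = "#2166ac", "FDR" = "#1b7837",
      "not selected" = "grey60")) +
    ggplot2::labs(x = "phecode", y = expression(-log[10](p)),
                  color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(bonferroni_threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(bonferroni_threshold),
                                 linetype = "dashed", color = "#2166ac")
  }
  p
}

#' Trace and posterior plots for a model fit
#'
#' @param object A [fit_bslmm()] result.
#' @param ... Unused.
#' @return A ggplot object: hyperparameter traces over retained draws.
#' @export
autoplot.bslmm_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$chains,
                              c("h", "rho", "log10_pi", "n_gamma"),
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$draw, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, color = "#2166ac") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained draw", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of standardized predicted scores
#'
#' Biomarkers dominated by a few large-effect SNPs produce visibly
#' multimodal predicted-score distributions; highly polygenic biomarkers
#' look approximately normal.
#'
#' @param scores A [project_scores()] result.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, bins = 50) {
  ggplot2::ggplot(tibble::as_tibble(scores),
                  ggplot2::aes(.data$standardized)) +
    ggplot2::geom_histogram(bins = bins, fill = "#2166ac", color = "white") +
    ggplot2::labs(x = "standardized predicted biomarker", y = "samples") +
    ggplot2::theme_minimal()
}
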