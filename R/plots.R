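#' @importFrom ggplot2 ggplot aes geom_point geom_violin geom_boxplot
#'   geom_histogram geom_vline geom_hline labs theme_minimal scale_color_manual
NULL

#' Volcano-style plot of differential-abundance results
#'
#' Rank-mean effect against permutation p, significant features
#' highlighted.
#'
#' @param object A `ruralindex_da`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.ruralindex_da <- function(object, ...) {
  df <- object$results
  ggplot(df, aes(x = .data$effect, y = -log10(pmax(.data$p_raw, 1e-6)),
                 color = .data$significant)) +
    geom_point(alpha = 0.7) +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = sprintf("rank-mean effect (%s - %s)", object$groups[1], object$groups[2]),
         y = expression(-log[10](p)), color = "dsFDR call") +
    theme_minimal()
}

#' Violin plot of index scores by group
#'
#' @param scores A tibble with `sample_id`, `score` and `group` (e.g. the
#'   `scores` element of a pipeline report).
#' @param metadata Optional metadata to supply `group` when absent.
#' @return A ggplot.
#' @export
plot_index_scores <- function(scores, metadata = NULL) {
  if (!"group" %in% names(scores)) {
    if (is.null(metadata)) abort("supply `metadata` to provide group labels")
    scores <- inner_join(scores, metadata[c("sample_id", "group")], by = "sample_id")
  }
  ggplot(scores, aes(x = .data$group, y = .data$score, fill = .data$group)) +
    geom_violin(alpha = 0.6) +
    geom_boxplot(width = 0.15, outlier.shape = NA, fill = "white") +
    labs(x = NULL, y = "index score (log rank ratio)") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Null distribution of the coupling permutation test
#'
#' @param object A `coupling_result`.
#' @param ... Ignored.
#' @return A ggplot with the observed correlation marked.
#' @export
autoplot.coupling_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$null_rho)) +
    geom_histogram(bins = 20, fill = "grey70", color = "white") +
    geom_vline(xintercept = object$rho_observed, color = "firebrick",
               linewidth = 1) +
    labs(x = "permutation Spearman rho", y = "count",
         subtitle = sprintf("observed rho = %.3f, p = %g",
                            object$rho_observed, object$p)) +
    theme_minimal()
}

#' Scatter plot of two contrasts' coefficients
#'
#' @param object A `ruralindex_concordance`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.ruralindex_concordance <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$coefficient_a, y = .data$coefficient_b,
                           color = .data$agree)) +
    geom_point(size = 2) +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_vline(xintercept = 0, linetype = 3) +
    scale_color_manual(values = c(`TRUE` = "steelblue", `FALSE` = "grey50")) +
    labs(x = "contrast A coefficient", y = "contrast B coefficient",
         color = "same direction",
         subtitle = sprintf("Spearman rho = %.3f (p = %.2g)", object$rho,
                            object$p_value)) +
    theme_minimal()
}
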