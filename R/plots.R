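#' Boxplots of methylation recovery by region class
#'
#' Draws the class-level recovery boxplots: one box per (sample, region
#' class) built from the same five-number summaries as
#' [summarize_recovery()] — quartile box and whiskers at the most extreme
#' values within 1.5 IQR.
#'
#' @param records An `mr_records` tibble from [recovery_table()].
#' @return A ggplot object.
#' @export
plot_recovery <- function(records) {
  s <- summarize_recovery(records)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$region_class,
                                  fill = .data$sample_id)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high),
      stat = "identity",
      position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_hline(yintercept = c(0, 100), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "methylation recovery (%)",
                  fill = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @rdname plot_recovery
#' @param object An `mr_records` tibble.
#' @param ... Unused.
#' @export
autoplot.mr_records <- function(object, ...) plot_recovery(object)

#' Heat map of a sample-by-sample correlation matrix
#'
#' @param x A `cor_matrix` from [spearman_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation <- function(x) {
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 3) +
    ggplot2::scale_fill_gradient(limits = c(min(df$rho, na.rm = TRUE), 1),
                                 low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' @rdname plot_correlation
#' @param object A `cor_matrix`.
#' @param ... Unused.
#' @export
autoplot.cor_matrix <- function(object, ...) plot_correlation(object)

#' Lollipop plot of a bisulfite clone pattern
#'
#' One row per passing clone, one point per CpG; filled points are
#' methylated calls, open points unmethylated, dots missing.
#'
#' @param object A `meth_pattern`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_pattern <- function(object, ...) {
  m <- object$states
  df <- tibble(clone = rep(rownames(m), times = ncol(m)),
               cpg = rep(seq_len(ncol(m)), each = nrow(m)),
               state = as.vector(m))
  df$clone <- factor(df$clone, levels = rev(rownames(m)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cpg, y = .data$clone)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$clone),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$state,
                                     fill = .data$state), size = 3) +
    ggplot2::scale_shape_manual(values = c(methylated = 21,
                                           unmethylated = 21,
                                           missing = 20)) +
    ggplot2::scale_fill_manual(values = c(methylated = "black",
                                          unmethylated = "white",
                                          missing = "grey70")) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(m))) +
    ggplot2::labs(x = "CpG", y = NULL,
                  title = sprintf("%s: %.1f%% methylated",
                                  object$amplicon$name,
                                  object$overall_percent)) +
    ggplot2::theme_minimal()
}
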