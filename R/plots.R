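#' Expression heatmap of family genes
#'
#' Tile heatmap of `log2(RPKM + 1)` across stages. The +1 offset keeps
#' undetected (zero) values finite; see the methods vignette for the
#' rationale.
#'
#' @param expr Expression tibble ([parse_expression_table()]).
#' @param order_by Optional character vector of gene_ids fixing row order
#'   (e.g. grouped by tandem repeat).
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(expr, order_by = NULL) {
  validate_expression(expr)
  long <- tidyr::pivot_longer(
    expr, -"gene_id",
    names_to = "stage", values_to = "rpkm"
  )
  long$stage <- factor(long$stage, levels = names(expr)[-1])
  lev <- order_by %||% rev(expr$gene_id)
  long$gene_id <- factor(long$gene_id, levels = lev)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$stage, y = .data$gene_id, fill = log2(.data$rpkm + 1)
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2(RPKM+1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plots for pipeline reports
#'
#' `autoplot()` on a report draws per-class divergence boxplots
#' (`type = "divergence"`) or the expression heatmap (`type = "expression"`).
#'
#' @param object A `"tandemdiv_report"`.
#' @param type Plot type.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tandemdiv_report
#' @export
autoplot.tandemdiv_report <- function(object, type = c("divergence", "expression"), ...) {
  type <- match.arg(type)
  if (type == "expression") {
    return(plot_expression_heatmap(object$expression))
  }
  if (is.null(object$divergence)) {
    abort("report carries no divergence results; run with CDS inputs")
  }
  d <- object$divergence
  if (!"pair_class" %in% names(d)) d$pair_class <- "all"
  long <- tidyr::pivot_longer(
    select(d, "pair_class", "pi", "ka", "ks"),
    c("pi", "ka", "ks"),
    names_to = "statistic", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$pair_class, y = .data$value, fill = .data$pair_class
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~ .data$statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
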