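# ggplot2 displays for the main result types.

#' Plot a coverage track region
#'
#' @param track Coverage track ([coverage_track()]).
#' @param chrom Chromosome to display.
#' @param xlim Optional `c(start, end)` window (0-based).
#' @return A ggplot object (step plot of fragment overlap).
#' @export
plot_coverage <- function(track, chrom, xlim = NULL) {
  t <- track[track$chrom == chrom, , drop = FALSE]
  if (!is.null(xlim)) t <- clip_runs(t, xlim[1], xlim[2])
  df <- tibble(pos = c(rbind(t$start, t$end)),
               count = rep(t$count, each = 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom),
                  y = "fragment overlap") +
    ggplot2::theme_minimal()
}

#' Plot a cumulative or average binding profile
#'
#' Works for [element_profile()] (offsets relative to the element 5' TSD)
#' and [motif_profile()] (offsets relative to the motif midpoint).
#'
#' @param profile Profile tibble with `offset` and `total`/`mean`.
#' @param stat Which column to draw, `"total"` or `"mean"`.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, stat = c("total", "mean")) {
  stat <- match.arg(stat)
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$offset, y = .data[[stat]])) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "offset (bp)",
                  y = sprintf("%s fragment overlap", stat)) +
    ggplot2::theme_minimal()
}

#' Plot enrichment results
#'
#' Bar chart of -log10 binomial P-values, filled by empirical-FDR
#' significance at the given threshold.
#'
#' @param results Tibble from [enrichment_table()].
#' @param fdr_threshold Significance threshold (default 0.01).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, fdr_threshold = 0.01) {
  results$significant <- !is.na(results$empirical_fdr) &
    results$empirical_fdr < fdr_threshold
  ggplot2::ggplot(results,
                  ggplot2::aes(x = stats::reorder(.data$name,
                                                  -.data$p_value),
                               y = -log10(pmax(.data$p_value, 1e-300)),
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#D55E00")) +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "binomial P"),
                  fill = sprintf("FDR < %g", fdr_threshold)) +
    ggplot2::theme_minimal()
}
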