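# ggplot2 helpers over the tabular results. These are thin: every figure
# is drawn from a tibble another function already returns.

#' Plot a metachromosome profile
#'
#' Line plot of per-bin values from [metabin_profile()], with the
#' centromeric bins marked.
#' @param profile tibble from [metabin_profile()].
#' @param cfg a [dg_config()].
#' @return a ggplot object.
#' @export
plot_metaprofile <- function(profile, cfg = dg_config()) {
  half <- cfg$n_metabins / 2
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_vline(xintercept = c(half - 1, half + 1),
                        linetype = "dashed", colour = "red", alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = mean(profile$value),
                        linetype = "dotted", colour = "blue") +
    ggplot2::labs(
      x = sprintf("meta-bin (0 = q telomere, %d = centromere, %d = p telomere)",
                  half, cfg$n_metabins),
      y = "mean value"
    ) +
    ggplot2::theme_minimal()
}

#' Plot windowed NAHR enrichment along a chromosome
#'
#' @param enrichment tibble from [window_enrichment()].
#' @param chrom chromosome to show (default: all, facetted).
#' @return a ggplot object.
#' @export
plot_window_enrichment <- function(enrichment, chrom = NULL) {
  if (!is.null(chrom)) {
    enrichment <- filter(enrichment, .data$chrom == !!chrom)
  }
  ggplot2::ggplot(
    filter(enrichment, !.data$undefined),
    ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = .data$enrichment)
  ) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "NAHR events / repeat elements") +
    ggplot2::theme_minimal()
}

#' Plot the MDS outlier screen
#'
#' @param mds tibble from [mds_outlier_screen()].
#' @return a ggplot object.
#' @export
plot_mds <- function(mds) {
  ggplot2::ggplot(mds, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                    colour = .data$outlier)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample_id),
                       vjust = -1, size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}

#' Plot the permutation null distribution against the observed overlap
#'
#' @param object a `dg_permtest`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dg_permtest <- function(object, ...) {
  df <- tibble(count = object$perm_counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "regions overlapping target (permuted)",
      y = "permutations",
      title = sprintf("observed = %d, empirical p = %.4g",
                      object$observed, object$p)
    ) +
    ggplot2::theme_minimal()
}
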