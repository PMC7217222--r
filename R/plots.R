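#' Manhattan-style plot of window variance explained
#'
#' Percentage of additive genetic variance per SNP window along the
#' genome, with the candidate threshold drawn as a horizontal line.
#'
#' @param scan a `window_scan` from [window_variance()]
#' @param threshold candidate threshold in percent (line; default 0.5)
#' @param trait optional trait name for the title
#' @return a ggplot object
#' @export
plot_window_scan <- function(scan, threshold = 0.5, trait = NULL) {
  df <- as.data.frame(scan)
  df$mid_bp <- (df$start_bp + df$end_bp) / 2
  df$chrom <- factor(df$chrom)
  ggplot2::ggplot(df, ggplot2::aes(x = mid_bp / 1e6,
                                   y = pct_variance,
                                   colour = chrom)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = "% additive genetic variance per window",
                  title = trait) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Triangle heatmap of pairwise LD in a region
#'
#' @param ld an `ld_result` from [pairwise_r2()]
#' @return a ggplot object (tile intensity proportional to r^2)
#' @export
plot_ld_heatmap <- function(ld) {
  pr <- ld$pairs
  if (nrow(pr) == 0) stop("no pairs to plot")
  ord <- ld$map$snp
  pr$xi <- match(pr$snp_i, ord)
  pr$xj <- match(pr$snp_j, ord)
  ggplot2::ggplot(pr, ggplot2::aes(x = xi, y = xj,
                                   fill = r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "marker index", y = "marker index",
                  fill = expression(r^2)) +
    ggplot2::theme_minimal()
}
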