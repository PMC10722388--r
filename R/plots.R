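#' Bar chart of per-module loss with the 3-SD band
#'
#' One bar per module (percent of members lost clade-wide), a solid line
#' at the cross-module mean, and dashed lines 3 SD either side of it;
#' modules outside the band are highlighted.
#'
#' @param object A `module_loss_summary` from [module_loss()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.module_loss_summary <- function(object, ...) {
  dat <- object$modules |>
    dplyr::mutate(module = factor(.data$module, levels = .data$module))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$module, y = .data$loss_percent,
                                    fill = .data$outlier)) +
    ggplot2::geom_col(show.legend = any(dat$outlier)) +
    ggplot2::geom_hline(yintercept = object$mean_percent, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(object$lower_3sd, object$upper_3sd),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey35", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "genes lost (%)", fill = "> 3 SD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}

#' KO/WT ratio plot with replicate SD error bars
#'
#' Points at the per-metabolite mean KO/WT ratio with ± SD error bars on
#' a log2 axis; the dashed line at 1 marks "no change".
#'
#' @param ratios Tibble from [ko_wt_ratio()].
#' @return A ggplot object.
#' @export
plot_ko_wt <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$metabolite, y = .data$ratio_mean)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$ratio_mean - .data$ratio_sd,
      ymax = .data$ratio_mean + .data$ratio_sd)) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "KO / WT ratio (mean ± SD)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Stacked fractional-labeling plot
#'
#' Stacked bars of the M+i fractional distribution per metabolite.
#'
#' @param fractions Tibble from [fractional_labeling()].
#' @return A ggplot object.
#' @export
plot_fractional_labeling <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$metabolite, y = .data$fraction,
                               fill = factor(.data$isotopologue))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of pool", fill = "isotopologue") +
    ggplot2::theme_minimal()
}

#' Plot a paralogue phylogram
#'
#' Draws the neighbour-joining tree with leaves coloured by single-linkage
#' cluster, via [ape::plot.phylo()].
#'
#' @param x A `paralog_cluster` from [build_phylogram()].
#' @param ... Passed on to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.paralog_cluster <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(2L, length(unique(x$clusters))), "Dark 3")
  ape::plot.phylo(x$tree, tip.color = cols[x$clusters[x$tree$tip.label]], ...)
  invisible(x)
}
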