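#' Plot an fd scan along the genome
#'
#' One point per window at its midpoint, faceted by chromosome; called
#' regions (if supplied) are shaded.
#'
#' @param fd_windows Output of [fd_scan()].
#' @param regions Optional regions from [call_introgressed_regions()].
#' @param threshold fd threshold drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_fd_scan <- function(fd_windows, regions = NULL, threshold = 0.5) {
  w <- dplyr::filter(fd_windows, !.data$excluded, !is.na(.data$fd))
  p <- ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                       y = .data$fd)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(f[d])) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
      inherit.aes = FALSE)
  }
  p
}

#' Plot a sweep scan as the joint outlier diagram
#'
#' log2 theta-pi ratio against Z(FST) with the empirical top-tail
#' thresholds; joint outlier windows highlighted.
#'
#' @param object A `sweep_scan` tibble from [sweep_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_scan <- function(object, ...) {
  w <- dplyr::filter(object, .data$included)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$log2_pi_ratio, y = .data$z_fst,
                                  colour = .data$outlier)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = attr(object, "log2_ratio_cut"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(object, "z_fst_cut"),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(log[2](theta[pi] ~ ratio)),
                  y = expression(Z(F[ST]))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot LD decay
#'
#' Mean r-squared per distance bin (bin midpoints).
#'
#' @param bins Output of [ld_decay()].
#' @param min_pairs Bins with fewer pairs are dropped.
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(bins, min_pairs = 10) {
  b <- dplyr::filter(bins, .data$n_pairs >= min_pairs)
  ggplot2::ggplot(b, ggplot2::aes(x = (.data$dist_lo + .data$dist_hi) / 2,
                                  y = .data$mean_r2)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance (bp)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
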