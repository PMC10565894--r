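#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a windowed introgression scan
#'
#' @param object An `intro_scan` tibble from [scan_windows()].
#' @param stat Column to plot (default `"fd"`).
#' @param ... Unused.
#' @return A ggplot: the statistic along window midpoints, faceted by contig.
#' @export
autoplot.intro_scan <- function(object, stat = "fd", ...) {
  d <- tibble::as_tibble(object)
  d$mid <- (d$start + d$end) / 2
  ggplot2::ggplot(d[!is.na(d[[stat]]), ],
                  ggplot2::aes(x = .data$mid, y = .data[[stat]])) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "window midpoint (bp)", y = stat) +
    ggplot2::theme_minimal()
}

#' Plot an epoch scan (mean f_d against net divergence)
#'
#' @param object An `epoch_scan` from [stratified_scan()].
#' @param ... Unused.
#' @return A ggplot of per-P1 mean f_d with 95% CIs over mean d_a.
#' @export
autoplot.epoch_scan <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_da, y = .data$mean_fd,
                                  label = .data$p1)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -1, size = 3) +
    ggplot2::labs(x = expression(paste("mean ", d[a], " (P1 vs P2)")),
                  y = expression(paste("mean ", f[d], " (95% CI)"))) +
    ggplot2::theme_minimal()
}

#' Plot EHH decay curves
#'
#' @param object An `ehh_curve` from [ehh()] or [ehh_decay()].
#' @param ... Unused.
#' @return A ggplot of EHH against position, one line per core allele when
#'   present.
#' @export
autoplot.ehh_curve <- function(object, ...) {
  d <- tibble::as_tibble(object)
  p <- if ("allele" %in% names(d)) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$ehh,
                                    colour = factor(.data$allele)))
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$ehh))
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "focal_pos"),
                        linetype = "dashed") +
    ggplot2::labs(x = "position (bp)", y = "EHH", colour = "core allele") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot mean f_d across recombination-rate quantile bins
#'
#' @param object A `recomb_bins` tibble from
#'   [recombination_quantile_bins()].
#' @param ... Unused.
#' @return A ggplot of per-bin mean f_d with 95% CIs.
#' @export
autoplot.recomb_bins <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$bin), y = .data$mean_fd)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "recombination-rate quantile bin",
                  y = expression(paste("mean ", f[d], " (95% CI)"))) +
    ggplot2::theme_minimal()
}
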