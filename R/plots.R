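#' Plot a perfusion-map slice
#'
#' @param object A [compute_maps()] result.
#' @param map Which map to draw.
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ctp_maps <- function(object, map = c("tmax", "cbf_rel", "cbv_rel", "mtt"),
                              slice = NULL, ...) {
  map <- match.arg(map)
  vol <- object[[map]]
  slice <- slice %||% ceiling(dim(vol)[1L] / 2)
  sl <- vol[slice, , ]
  df <- tidyr::expand_grid(y = seq_len(nrow(sl)), x = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  lab <- c(tmax = "Tmax (s)", cbf_rel = "relative CBF (%)",
           cbv_rel = "relative CBV (%)", mtt = "MTT (s)")[[map]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20", name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s, slice %d", lab, slice)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of paired volumes
#'
#' @param reference,test Paired measurements (e.g. core volumes at 1.5 s and
#'   at a reduced sampling).
#' @param label Axis label for the measured quantity.
#' @return A ggplot object with the mean difference and 1.96 SD limits.
#' @export
plot_bland_altman <- function(reference, test, label = "volume (mL)") {
  ba <- bland_altman(reference, test)
  md <- mean(ba$difference)
  lim <- 1.96 * stats::sd(ba$difference)
  ggplot2::ggplot(ba, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = md, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(md - lim, md + lim), linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = sprintf("mean of pair, %s", label),
                  y = sprintf("test - reference, %s", label)) +
    ggplot2::theme_minimal()
}

#' Agreement metrics versus subsampling factor
#'
#' Line plot of ICC, median difference and SD of differences across
#' subsampling factors, faceted by metric and stratified by scan quality --
#' the summary view of how agreement degrades with coarser sampling.
#'
#' @param agreement A [cohort_agreement()] table.
#' @return A ggplot object.
#' @export
plot_agreement <- function(agreement) {
  long <- tidyr::pivot_longer(agreement, c("icc", "median_diff", "sd_diff"),
                              names_to = "statistic")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$factor, y = .data$value,
                                     colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(statistic ~ metric, scales = "free_y") +
    ggplot2::labs(x = "subsampling factor", y = NULL, colour = "scan quality") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ctp_experiment <- function(object, ...) plot_agreement(object$agreement)
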