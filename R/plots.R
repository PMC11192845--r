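# Diagnostic plots.

#' Plot the ratio distribution of per-nucleus scores
#'
#' Histogram of the perinuclear/central intensity ratios with the
#' classification cutoff marked; excluded nuclei are dropped.
#'
#' @param object A `perinuc_scores` tibble from [score_image()].
#' @param bins Number of histogram bins; default 30.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perinuc_scores <- function(object, bins = 30, ...) {
  cutoff <- attr(object, "cutoff") %||% 2
  df <- as_tibble(object) %>% filter(!.data$excluded)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40", color = "white") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = "perinuclear / central intensity ratio",
                  y = "nuclei",
                  title = sprintf("%d nuclei, cutoff %.3g", nrow(df), cutoff))
  if ("condition" %in% names(df))
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition))
  p
}

#' Plot a ring partition
#'
#' Raster view of the concentric elliptic regions of one nucleus.
#'
#' @param partition A [partition_rings()] result.
#' @return A ggplot object.
#' @export
plot_ring_partition <- function(partition) {
  stopifnot(inherits(partition, "ring_partition"))
  lab <- partition$labels
  idx <- which(lab > 0, arr.ind = TRUE)
  df <- tibble(x = idx[, 2] - 1, y = idx[, 1] - 1,
               region = factor(lab[idx],
                               labels = paste("ring", sort(unique(lab[idx])))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = NULL)
}

#' Overlay detected spots on an intensity channel
#'
#' @param channel Numeric intensity matrix.
#' @param spots A [detect_spots()] result.
#' @param downsample Keep every n-th pixel of the background raster for
#'   speed; default 1 (all pixels).
#' @return A ggplot object.
#' @export
plot_spots <- function(channel, spots, downsample = 1) {
  ri <- seq(1, nrow(channel), by = downsample)
  ci <- seq(1, ncol(channel), by = downsample)
  df <- expand.grid(y = ri - 1, x = ci - 1)
  df$intensity <- as.vector(channel[ri, ci])
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = as_tibble(spots),
                        ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 1, color = "red", size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}
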