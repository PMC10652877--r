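# ggplot2 visualisations. Seizure classes keep a fixed colour convention:
# tonic-clonic green, hyperkinetic blue, tonic orange; testing-phase points
# are drawn in lighter shades of the training colours.

seizure_palette <- c(tonic_clonic = "#1b9e77", hyperkinetic = "#2c7fb8",
                     tonic = "#e6823c")
seizure_palette_light <- c(tonic_clonic = "#a6dec9", hyperkinetic = "#a8c8e8",
                           tonic = "#f5cfa8")

#' Plot a motion signal
#'
#' Burn-in frames of the background model are drawn semi-transparent.
#' @param signal Motion-signal tibble from [extract_motion_signal()] (one or
#'   several clips bound together).
#' @return A ggplot object.
#' @export
plot_motion <- function(signal) {
  ggplot2::ggplot(signal, ggplot2::aes(x = .data$time_s, y = .data$motion)) +
    ggplot2::geom_line(ggplot2::aes(alpha = !.data$burnin), linewidth = 0.3,
                       show.legend = FALSE) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3)) +
    ggplot2::facet_wrap(~clip_id, scales = "free_x") +
    ggplot2::labs(x = "time (s)", y = "moving-pixel proportion") +
    ggplot2::theme_minimal()
}

#' Plot an oscillation signal
#'
#' Horizontal line: the ictal-oscillation filter threshold.
#' @param signal Oscillation tibble from [extract_oscillation_signal()].
#' @export
plot_oscillation <- function(signal) {
  thr <- attr(signal, "threshold_hz") %||% 2.5
  ggplot2::ggplot(signal,
                  ggplot2::aes(x = .data$window_end_s, y = .data$freq_hz)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$osc_fraction), width = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "red") +
    ggplot2::scale_fill_gradient(low = "grey80", high = "#2c7fb8",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~clip_id) +
    ggplot2::labs(x = "window end (s)", y = "oscillation frequency (Hz)",
                  fill = "oscillating\nfraction") +
    ggplot2::theme_minimal()
}

#' Cluster-diagram plot of a 2-D embedding
#'
#' Training clips are drawn in strong shades, testing clips in light shades
#' of the same class colour. The embedding axes are unitless principal
#' components and are deliberately left unlabelled beyond their names.
#'
#' @param embedding Tibble from [project_pca()] (train and test rows may be
#'   bound together).
#' @param clusters Optional [agglomerate()] result; adds hull outlines per
#'   discovered cluster.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, clusters = NULL) {
  emb <- embedding
  emb$shade <- paste(emb$label, ifelse(emb$phase == "train", "train", "test"))
  pal <- c(stats::setNames(seizure_palette,
                           paste(names(seizure_palette), "train")),
           stats::setNames(seizure_palette_light,
                           paste(names(seizure_palette_light), "test")))
  p <- ggplot2::ggplot(emb, ggplot2::aes(x = .data$pc1, y = .data$pc2))
  if (!is.null(clusters)) {
    emb$cluster <- factor(clusters$assignments)
    hull <- dplyr::slice(dplyr::group_by(emb, .data$cluster),
                         grDevices::chull(.data$pc1, .data$pc2))
    p <- p + ggplot2::geom_polygon(
      data = hull, ggplot2::aes(group = .data$cluster),
      fill = NA, colour = "grey40", linetype = 3)
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$shade,
                                     shape = .data$phase), size = 2) +
    ggplot2::scale_colour_manual(values = pal, name = "seizure type") +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' @rdname plot_cv
#' @param object A `cv_result`.
#' @param ... Unused.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) plot_cv(object)

#' Per-class accuracy/F1 plot with confidence intervals
#' @param result A `cv_result` from [repeated_cv()].
#' @export
plot_cv <- function(result) {
  td <- tidy(result)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$class, y = .data$mean,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$ci_halfwidth,
                                        ymax = .data$mean + .data$ci_halfwidth),
                           width = 0.2) +
    ggplot2::scale_fill_manual(values = seizure_palette, guide = "none") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
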