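#' Plot a tiling activity profile
#'
#' One trace per tile size, on a log activity scale, with the basal minP
#' level as a dashed reference line.
#'
#' @param profile Tibble with `position`, `activity`, `size` (and
#'   optionally `orientation`).
#' @param minP Optional basal activity drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_tiling_profile <- function(profile, minP = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$position, y = .data$activity,
                                    colour = factor(.data$size))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "tile position (bp)", y = "activity (RNA/DNA)",
                  colour = "tile size (bp)") +
    ggplot2::theme_minimal()
  if (!is.null(minP)) {
    p <- p + ggplot2::geom_hline(yintercept = minP, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' Plot variant effects along a CRE
#'
#' Position-by-alternative heatmap of log2 fold-changes.
#'
#' @param effects A [variant_effects()] tibble.
#' @return A ggplot object.
#' @export
plot_variant_effects <- function(effects) {
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = .data$position, y = .data$alt,
                               fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "position (bp)", y = "alternative",
                  fill = "log2 FC vs WT") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.variant_effects <- function(object, ...) plot_variant_effects(object)

#' Plot an activity-size Pareto front
#'
#' All points plus the front as a step line.
#'
#' @param points Tibble with `length`, `activity`, optionally `source`.
#' @param front Optional precomputed [pareto_front()]; computed if NULL.
#' @return A ggplot object.
#' @export
plot_pareto <- function(points, front = NULL) {
  front <- front %||% pareto_front(points)
  aes_pt <- if ("source" %in% names(points)) {
    ggplot2::aes(x = .data$length, y = .data$activity, colour = .data$source)
  } else {
    ggplot2::aes(x = .data$length, y = .data$activity)
  }
  ggplot2::ggplot(points, aes_pt) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_step(data = front,
                       ggplot2::aes(x = .data$length, y = .data$activity),
                       direction = "hv", inherit.aes = FALSE,
                       linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "length (bp)", y = "activity (RNA/DNA)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.compaction_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$length, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "sequence length (bp)", y = "scorer value",
                  title = "greedy compaction trajectory") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.epistasis_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$tfbs_i, y = .data$tfbs_j,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object[!is.na(object$below_minP) &
                                        object$below_minP, ],
                        shape = 4, size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = "log2 obs/exp",
                  caption = "x: multiplicative expectation below minP") +
    ggplot2::theme_minimal()
}
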