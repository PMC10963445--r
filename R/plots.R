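#' Plot a fitted HMM over its observations
#'
#' Observations coloured by their decoded (Viterbi) state, with the fitted
#' state means as dashed horizontal lines.
#'
#' @param object An `hmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hmm_fit
#' @export
autoplot.hmm_fit <- function(object, ...) {
  d <- augment(object)
  K <- object$params$n_states
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$map_state))) +
    ggplot2::geom_hline(yintercept = object$params$means,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Year", y = "Observation", colour = "State",
                  title = sprintf("%d-state HMM (logL %.1f, AIC %.1f)",
                                  K, object$loglik, object$aic)) +
    ggplot2::theme_minimal()
}

#' Plot a running-correlation test
#'
#' Observed running correlations against window centre, with the block
#' bootstrap null threshold as horizontal lines and exceeding windows
#' highlighted.
#'
#' @param object A `running_cor_test` from
#'   [block_bootstrap_significance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot running_cor_test
#' @export
autoplot.running_cor_test <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes(x = .data$center, y = .data$r)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$null_threshold,
                        linetype = "dotted", colour = "red") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$exceeds)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "Window centre (year)", y = "Pearson r",
                  colour = sprintf("|r| > %d%% null",
                                   round(100 * object$level)),
                  title = sprintf("Running climate-growth correlation (MK p = %.3g)",
                                  object$mk_p)) +
    ggplot2::theme_minimal()
}

#' Map a per-cell correlation or change layer
#'
#' Tile map of one numeric layer of a per-cell table (correlation maps,
#' change maps), with optional significance stippling.
#'
#' @param map Tibble with `lat`, `lon`, the layer column, and optionally
#'   `sig`.
#' @param layer Name of the column to fill by (default `"r"`).
#' @return A ggplot object.
#' @export
plot_cell_map <- function(map, layer = "r") {
  stopifnot_cols(map, c("lat", "lon", layer), "map")
  p <- ggplot2::ggplot(map, ggplot2::aes(x = .data$lon, y = .data$lat,
                                         fill = .data[[layer]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = layer) +
    ggplot2::theme_minimal()
  if ("sig" %in% names(map)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(map, .data$sig %in% TRUE),
      ggplot2::aes(x = .data$lon, y = .data$lat),
      inherit.aes = FALSE, shape = 4, size = 1)
  }
  p
}

#' Plot per-class phenology sensitivity
#'
#' Mean regression slope (alpha, days per degC) per forest cover class with
#' the interquartile range.
#'
#' @param by_class Per-class summary tibble from [classify_and_summarize()].
#' @return A ggplot object.
#' @export
plot_class_sensitivity <- function(by_class) {
  stopifnot_cols(by_class, c("cover_class", "alpha_mean"), "by_class")
  ggplot2::ggplot(by_class,
                  ggplot2::aes(x = .data$cover_class, y = .data$alpha_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$alpha_q25,
                                          ymax = .data$alpha_q75)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Cover class",
                  y = expression(alpha ~ "(days per" * degree * "C)")) +
    ggplot2::theme_minimal()
}
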