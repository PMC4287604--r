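# ggplot2 displays for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a correlogram decomposition
#'
#' Raw, shuffle-predictor and noise correlograms of a pair on one axis.
#'
#' @param object an `ell_correlograms` from [pair_correlograms()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.ell_correlograms <- function(object, ...) {
  long <- tidyr::pivot_longer(object$cross, -"lag_ms",
                              names_to = "component",
                              values_to = "value")
  long$component <- factor(long$component,
                           levels = c("raw", "shuffle", "noise"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$lag_ms, y = .data$value,
                               colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "lag (ms)",
                  y = "coincidences relative to chance (Hz)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ell_correlogram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$lag_ms, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "lag (ms)",
                  y = "coincidences relative to chance (Hz)",
                  title = attr(object, "kind")) +
    ggplot2::theme_minimal()
}

#' Plot the weight profile against stimulus phase
#'
#' The equilibrium profile of the parallel-fiber weights as a function
#' of each granule cell's preferred stimulus phase, with the stimulus
#' sinusoid overlaid: after training the profile is a negative image of
#' the stimulus.
#'
#' @param weights a 2 x n weight matrix or an `ell_training`
#' @param f stimulation frequency (Hz); taken from the training object
#'   when one is given
#' @return a ggplot
#' @export
plot_weight_profile <- function(weights, f = NULL) {
  if (inherits(weights, "ell_training")) {
    f <- weights$f
    weights <- weights$weights
  }
  stopifnot(!is.null(f))
  wp <- weight_profile(weights, f)
  amp <- max(wp$weight) / 2
  ggplot2::ggplot(wp, ggplot2::aes(x = .data$phase, y = .data$weight)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$sp_id)),
                        size = 0.8) +
    ggplot2::stat_function(fun = function(x) amp * (1 + sin(2 * pi * x)),
                           linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "granule stimulus phase (cycles)", y = "weight",
                  colour = "SP cell") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ell_sweep <- function(object, ...) {
  kind <- attr(object, "sweep")
  if (identical(kind, "rho")) {
    long <- tidyr::pivot_longer(
      object[, c("rho", "noise_ratio", "signal_ratio")],
      -"rho", names_to = "coefficient", values_to = "ratio")
    ggplot2::ggplot(long,
                    ggplot2::aes(x = .data$rho, y = .data$ratio,
                                 colour = .data$coefficient)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = 1, linetype = 3) +
      ggplot2::labs(x = expression(rho ~ (mu * A / cm^2)),
                    y = "global / local ratio") +
      ggplot2::theme_minimal()
  } else {
    xy <- if (identical(kind, "c_e")) c("c", "e") else c("c", "f")
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data[[xy[1]]], y = .data[[xy[2]]],
                                 fill = .data$difference)) +
      ggplot2::geom_tile() +
      ggplot2::labs(fill = "local - global\nnoise correlation") +
      ggplot2::theme_minimal()
  }
}

#' Raster plot of granule-cell responses over stimulus cycles
#'
#' @param gc_spikes the `gc_spikes` element of an `ell_sim` (requires
#'   `record_gc = TRUE`)
#' @param f stimulation frequency (Hz)
#' @param cells which granule cells (of bank 1) to show
#' @return a ggplot
#' @export
plot_granule_raster <- function(gc_spikes, f, cells = c(1, 26, 51, 76)) {
  P <- 1000 / f
  sub <- gc_spikes[gc_spikes$bank == 1 & gc_spikes$cell %in% cells, ]
  sub$cycle <- floor(sub$spike_time_ms / P)
  sub$phase <- (sub$spike_time_ms %% P) / P
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$phase, y = .data$cycle)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::facet_wrap(~cell, nrow = 1) +
    ggplot2::labs(x = "stimulus phase (cycles)", y = "cycle") +
    ggplot2::theme_minimal()
}
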