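# broom-style tidiers for the fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correlogram decomposition
#'
#' @param x an `ell_correlograms`
#' @param ... unused
#' @return a long tibble: `lag_ms`, `pair` (cross/auto1/auto2),
#'   `component` (raw/shuffle/noise), `value`
#' @export
tidy.ell_correlograms <- function(x, ...) {
  purrr::map_dfr(c("cross", "auto1", "auto2"), function(p) {
    long <- tidyr::pivot_longer(x[[p]], -"lag_ms",
                                names_to = "component",
                                values_to = "value")
    long$pair <- p
    long[, c("lag_ms", "pair", "component", "value")]
  })
}

#' @export
glance.ell_correlograms <- function(x, ...) {
  co <- correlation_coefficients(x)
  co$n_cycles <- x$meta$M
  co$rate1_hz <- x$meta$rate1_hz
  co$rate2_hz <- x$meta$rate2_hz
  co
}

#' Tidy a training run
#'
#' @param x an `ell_training`
#' @param ... unused
#' @return long tibble of the weight snapshots: `time_s`, `sp_id`,
#'   `granule_id`, `phase`, `weight`
#' @export
tidy.ell_training <- function(x, ...) {
  n_gc <- ncol(x$weights)
  ph <- presyn_burst_phase(x$f, n_gc) / (1000 / x$f)
  purrr::map_dfr(seq_along(x$snapshot_times_s), function(i) {
    tibble::tibble(
      time_s = x$snapshot_times_s[i],
      sp_id = rep(1:2, each = n_gc),
      granule_id = rep(seq_len(n_gc), 2),
      phase = rep(ph, 2),
      weight = x$snapshots[i, ]
    )
  })
}

#' @export
glance.ell_training <- function(x, ...) {
  tibble::tibble(
    duration_s = x$duration_s,
    mean_weight = mean(x$weights),
    negative_image_index = negative_image_index(x$weights, x$f),
    n_bursts_sp1 = sum(x$bursts$neuron_id == 1),
    n_bursts_sp2 = sum(x$bursts$neuron_id == 2),
    frac_4spike = mean(x$bursts$size == 4)
  )
}

#' @export
print.ell_training <- function(x, ...) {
  g <- glance(x)
  cat("ELL training run: ", x$duration_s, " s at f = ", x$f, " Hz\n",
      "  mean weight ", signif(g$mean_weight, 3),
      ", negative-image index ", signif(g$negative_image_index, 3), "\n",
      "  bursts: ", g$n_bursts_sp1, " (SP1), ", g$n_bursts_sp2,
      " (SP2), fraction 4-spike ", signif(g$frac_4spike, 3), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.ell_sim <- function(x, ...) {
  n <- table(factor(x$spikes$neuron_id, levels = 1:2))
  cat("ELL network simulation: ", x$duration_s, " s, ", x$geometry,
      " geometry\n", "  SP spikes: ", n[[1]], " / ", n[[2]],
      " (rates ", signif(n[[1]] / x$duration_s, 3), " / ",
      signif(n[[2]] / x$duration_s, 3), " Hz)\n", sep = "")
  invisible(x)
}

#' @importFrom rlang .data
NULL
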