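# Spike-table input/output. The on-disk schema is the package-wide spike
# table: neuron_id, trial_id, spike_time_ms — one row per spike — so the
# analysis functions are agnostic to whether trains came from the
# simulator or elsewhere.

#' Read and write spike tables
#'
#' Tab-separated text with columns `neuron_id`, `trial_id`,
#' `spike_time_ms`; round-trips losslessly (times written at full
#' precision).
#'
#' @param spikes a spike table
#' @param path file path
#' @return `write_spike_trains()` returns `path` invisibly;
#'   `read_spike_trains()` returns the spike table as a tibble.
#' @export
write_spike_trains <- function(spikes, path) {
  stopifnot(all(c("neuron_id", "trial_id", "spike_time_ms") %in%
                  names(spikes)))
  readr::write_tsv(spikes[, c("neuron_id", "trial_id", "spike_time_ms")],
                   path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    neuron_id = readr::col_integer(),
    trial_id = readr::col_integer(),
    spike_time_ms = readr::col_double()
  ))
}

#' Read and write weight trajectories
#'
#' Long-format tabular text: `time_s`, `sp_id`, `granule_id`, `weight`;
#' suitable for freezing or resuming a training run.
#'
#' @param training an `ell_training` from [train_network()]
#' @param path file path
#' @return `write_weight_trajectory()` returns `path` invisibly;
#'   `read_weight_trajectory()` returns a tibble.
#' @export
write_weight_trajectory <- function(training, path) {
  stopifnot(inherits(training, "ell_training"))
  n_gc <- ncol(training$weights)
  tab <- purrr::map_dfr(seq_along(training$snapshot_times_s), function(i) {
    tibble::tibble(
      time_s = training$snapshot_times_s[i],
      sp_id = rep(1:2, each = n_gc),
      granule_id = rep(seq_len(n_gc), 2),
      weight = training$snapshots[i, ]
    )
  })
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_weight_trajectory
#' @export
read_weight_trajectory <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    sp_id = readr::col_integer(),
    granule_id = readr::col_integer(),
    weight = readr::col_double()
  ))
}
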