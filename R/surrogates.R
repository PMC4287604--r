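# Doubly stochastic surrogate spike-train pairs with independently
# dialled signal and noise correlations, used to validate the analysis
# stage without running the network model.

#' Surrogate pair specification
#'
#' Both neurons share the instantaneous rate
#' `lambda(t) = rectify(lambda0 * (1 + m_sig * sin(2 pi f t) + m_noise * eta(t)))`
#' where `eta` is a smooth shared noise redrawn independently on every
#' trial. `m_sig` controls the stimulus-locked (signal) correlation and
#' `m_noise` the shared trial-to-trial (noise) correlation; given the
#' rate, the two neurons are independent Poisson processes.
#'
#' @param base_rate_hz mean rate `lambda0` (Hz)
#' @param m_sig modulation depth of the common sinusoid, in `[0, 1]`
#' @param m_noise gain of the shared rate noise (>= 0)
#' @param f modulation frequency (Hz)
#' @param noise_bw_hz bandwidth of the shared rate noise (Hz)
#' @param n_trials number of trials
#' @param trial_duration_s trial duration (s)
#' @param seed RNG seed
#' @return a list of class `surrogate_spec`
#' @export
surrogate_spec <- function(base_rate_hz = 20, m_sig = 0.5, m_noise = 0.5,
                           f = 4, noise_bw_hz = 10, n_trials = 20,
                           trial_duration_s = 10, seed = 1) {
  stopifnot(base_rate_hz > 0, m_sig >= 0, m_sig <= 1, m_noise >= 0,
            f > 0, noise_bw_hz > 0, n_trials >= 1, trial_duration_s > 0)
  structure(as.list(environment()), class = "surrogate_spec")
}

#' Generate a surrogate spike-train pair
#'
#' Thinning-based sampling at the analysis binwidth: per-bin counts are
#' Poisson with mean `lambda(t) dt`, and spike times are placed
#' uniformly within their bin. Rectification handles negative
#' instantaneous rates.
#'
#' @param spec a [surrogate_spec()]
#' @param dt_ms sampling resolution (ms)
#' @return a spike table (`neuron_id`, `trial_id`, `spike_time_ms`) for
#'   2 neurons x `n_trials`
#' @export
generate_pair <- function(spec, dt_ms = 0.5) {
  stopifnot(inherits(spec, "surrogate_spec"))
  set.seed(spec$seed)
  dur_ms <- spec$trial_duration_s * 1000
  n_bins <- as.integer(round(dur_ms / dt_ms))
  tt <- (seq_len(n_bins) - 0.5) * dt_ms / 1000
  sig <- spec$m_sig * sin(2 * pi * spec$f * tt)
  fs <- 1000 / dt_ms
  bt <- signal::butter(2, min(spec$noise_bw_hz / (fs / 2), 0.99),
                       type = "low")
  purrr::map_dfr(seq_len(spec$n_trials), function(tr) {
    eta <- as.numeric(signal::filter(bt, stats::rnorm(n_bins + 4000)))
    eta <- eta[-seq_len(4000)]
    eta <- (eta - mean(eta)) / stats::sd(eta)
    lam <- pmax(0, spec$base_rate_hz * (1 + sig + spec$m_noise * eta))
    purrr::map_dfr(1:2, function(nn) {
      counts <- stats::rpois(n_bins, lam * dt_ms / 1000)
      idx <- rep.int(seq_len(n_bins), counts)
      times <- sort((idx - 1 + stats::runif(length(idx))) * dt_ms)
      tibble::tibble(neuron_id = nn, trial_id = tr, spike_time_ms = times)
    })
  })
}

#' Tiny hand-checkable fixture for the correlogram pipeline
#'
#' A deterministic two-cycle spike set whose raw, shuffle and noise
#' correlograms can be enumerated by hand (10 phase bins of 10 ms per
#' cycle, stimulus period 100 ms), together with the bin parameters to
#' analyse it.
#'
#' @return a list with `spikes`, `f`, `trial_duration_s`, `dt_ms`
#' @export
known_answer_fixture <- function() {
  # neuron 1: cycle 1 spikes in bins 2 and 7; cycle 2 spikes in bins 2, 5
  # neuron 2: cycle 1 spikes in bins 2 and 9; cycle 2 spike  in bin  2
  # (bin b covers [10 (b-1), 10 b) ms; spikes placed at bin centres)
  mk <- function(bins, cyc) (cyc - 1) * 100 + (bins - 1) * 10 + 5
  spikes <- tibble::tibble(
    neuron_id = c(rep(1L, 4), rep(2L, 3)),
    trial_id = 1L,
    spike_time_ms = c(mk(c(2, 7), 1), mk(c(2, 5), 2),
                      mk(c(2, 9), 1), mk(2, 2))
  )
  list(spikes = spikes[order(spikes$neuron_id, spikes$spike_time_ms), ],
       f = 10, trial_duration_s = 0.2, dt_ms = 10)
}
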