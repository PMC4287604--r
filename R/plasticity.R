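# Burst classification and the anti-Hebbian burst-timing-dependent
# plasticity rule at parallel-fiber synapses.

#' Classify bursts in a spike train
#'
#' Online, exclusive burst assignment: on each new spike, the spike and
#' its three predecessors form a 4-spike burst if none of them already
#' belongs to a burst and the first and last are within 45 ms; failing
#' that, the 4th- and 5th-most-recent spikes form a 2-spike burst if
#' neither is assigned and they are within 15 ms. The 4-spike burst
#' takes priority, and a spike can belong to at most one burst.
#'
#' @param spike_times spike times (ms), strictly increasing
#' @return a tibble with one row per burst: `onset_ms` (time of the
#'   first spike of the burst), `size` (2 or 4), and `members` (list of
#'   spike indices)
#' @export
classify_bursts <- function(spike_times) {
  res <- classify_bursts_cpp(as.numeric(spike_times))
  n_burst <- length(res$onset)
  members <- lapply(seq_len(n_burst), function(b) which(res$burst_id == b))
  tibble::tibble(onset_ms = res$onset, size = res$size,
                 members = members)
}

#' Plasticity coincidence kernel
#'
#' The timing dependence of the burst-induced depression: a box window
#' of total length `L_W` centred on the postsynaptic burst onset, i.e.
#' the update is applied when
#' `|t_burst_pre - t_burst_post| <= L_W / 2` (circularly in the stimulus
#' period, since presynaptic burst times recur every cycle).
#'
#' @param delta_ms circular time difference `t_pre - t_post` (ms)
#' @param L_W total window length (ms)
#' @return 1 inside the window, 0 outside
#' @export
btdp_kernel <- function(delta_ms, L_W) {
  as.numeric(abs(delta_ms) <= L_W / 2)
}

#' Presynaptic burst times of the granule bank
#'
#' The presynaptic burst onset of granule cell `i` is the time at which
#' its delayed sinusoidal input reaches its local maximum:
#' `d_i + P/4 (mod P)`.
#'
#' @param f stimulation frequency (Hz)
#' @param n bank size
#' @return phase times within one period (ms), one per granule cell
#' @export
presyn_burst_phase <- function(f, n = 100) {
  P <- 1000 / f
  (granule_delay(seq_len(n), f, n) + P / 4) %% P
}

#' Burst-induced depression of parallel-fiber weights
#'
#' Applies one postsynaptic burst to a bank of weights: every weight
#' whose presynaptic burst time falls within the coincidence window of
#' the burst class is depressed multiplicatively by the class gain
#' (`w <- w * (1 - eta_g)`), so weights stay positive and the
#' equilibrium profile against the slow potentiation is graded,
#' `w_eq = 1 / (1 + eta_g * r_burst * tau_w)`, with `r_burst` the
#' in-window burst rate seen by that synapse.
#'
#' @param weights numeric vector of weights in `[0, 1]`
#' @param burst_onset_ms onset time of the SP burst (ms)
#' @param burst_size 2 or 4
#' @param f stimulation frequency (Hz)
#' @param plasticity [plasticity_params()]
#' @param tpre_ms presynaptic burst phase times, default
#'   [presyn_burst_phase()] for the bank size
#' @return the updated weight vector
#' @export
depress_weights <- function(weights, burst_onset_ms, burst_size, f,
                            plasticity = plasticity_params(),
                            tpre_ms = presyn_burst_phase(f, length(weights))) {
  stopifnot(burst_size %in% c(2, 4), all(weights >= 0), all(weights <= 1))
  P <- 1000 / f
  eta <- if (burst_size == 4) plasticity$eta_4 else plasticity$eta_2
  L_W <- if (burst_size == 4) plasticity$L_W4 else plasticity$L_W2
  delta <- (tpre_ms - burst_onset_ms) %% P
  delta <- ifelse(delta > P / 2, delta - P, delta)
  weights * (1 - eta * btdp_kernel(delta, L_W))
}

#' Non-associative potentiation
#'
#' Slow relaxation of every weight toward the upper bound 1 with time
#' constant `tau_w`: `dw/dt = (1 - w) / tau_w`. Applied here in closed
#' form over an interval `dt_s`.
#'
#' @param weights numeric vector or matrix of weights
#' @param dt_s elapsed time (s)
#' @param plasticity [plasticity_params()]
#' @return updated weights
#' @export
potentiate_weights <- function(weights, dt_s,
                               plasticity = plasticity_params()) {
  1 - (1 - weights) * exp(-dt_s / plasticity$tau_w)
}
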