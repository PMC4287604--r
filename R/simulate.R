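# Wrapper around the compiled Euler-Maruyama core, plus small reference
# implementations of the single-cell building blocks (alpha kernel, DAP
# current, AMPA conductance, granule delays) used for oracle tests and
# documentation.

build_core_pars <- function(config, stim, duration_s, weights, plasticity,
                            seed, trial, snapshot_times_s = numeric(),
                            record_gc = FALSE, record_v = FALSE,
                            burn_ms = 100) {
  sp <- config$sp
  gc <- config$granule
  pl <- config$plasticity
  no <- config$noise
  feedback <- identical(stim$geometry, "global")
  flt <- butter_filter(no$cutoff_hz, config$dt, no$order)
  if (is.null(weights)) {
    weights <- matrix(1, nrow = 2, ncol = gc$count_per_sp)
  }
  stopifnot(nrow(weights) == 2, ncol(weights) == gc$count_per_sp,
            all(weights >= 0), all(weights <= 1))
  list(
    dt = config$dt, duration_ms = duration_s * 1000, burn_ms = burn_ms,
    f = stim$f, kappa = stim$kappa, feedback = feedback,
    c = no$c, e = no$e, sigma = sp$sigma, rho = gc$rho,
    n_gc = gc$count_per_sp,
    C = sp$C, g_leak = sp$g_leak, E_leak = sp$E_leak, I = sp$I,
    V_threshold = sp$V_threshold, V_rest = sp$V_rest, r_s = sp$r_s,
    g_GABA = if (feedback) sp$g_GABA else 0,
    E_GABA = sp$E_GABA, E_AMPA = sp$E_AMPA,
    g_max = if (feedback) sp$g_max else 0,
    tau_AMPA = sp$tau_AMPA, I_gc = gc$I_gc, kappa_gc = gc$kappa_gc,
    A = sp$A, B = sp$B, D = sp$D, E = sp$E, gamma = sp$gamma,
    alpha = sp$alpha, tau = sp$tau,
    plasticity = isTRUE(plasticity),
    eta_2 = pl$eta_2, eta_4 = pl$eta_4, L_W2 = pl$L_W2, L_W4 = pl$L_W4,
    tau_w = pl$tau_w,
    weights = weights, record_gc = record_gc, record_v = record_v,
    snapshot_times = snapshot_times_s * 1000,
    seed = seed, trial = trial,
    filt_b = flt$b, filt_a = flt$a, filt_scale = flt$scale
  )
}

#' Simulate the two-cell ELL network
#'
#' Integrates the coupled stochastic dynamics of the two SP cells (and,
#' under global geometry, the two disjoint granule-cell banks) for one
#' trial with the Euler-Maruyama scheme at step `config$dt`. A spike is
#' registered when the voltage reaches threshold at the end of a step;
#' the membrane is then reset to rest and clamped for the somatic
#' refractory period. Each call burns in the noise filters and membrane
#' state before `t = 0`, and the stimulus phase is zero at `t = 0` so
#' cycles align across trials.
#'
#' @param config a [model_config()]
#' @param stim a [stimulus_spec()]; `geometry = "local"` disconnects the
#'   feedback (`g_max = g_GABA = 0`, granule bank silent)
#' @param weights 2 x `count_per_sp` matrix of synaptic weights in
#'   `[0, 1]`; defaults to all 1
#' @param plasticity apply the burst-timing-dependent plasticity rule
#'   during this run
#' @param seed,trial master seed and trial index; together they select
#'   independent noise substreams
#' @param snapshot_times_s weight snapshot times (s), used during training
#' @param record_gc also record granule spike times
#' @param record_v also record the SP membrane voltage traces (short runs
#'   only)
#' @return a list of class `ell_sim` with elements `spikes` (tibble:
#'   `neuron_id`, `trial_id`, `spike_time_ms`), `weights`, and optionally
#'   `gc_spikes`, `v`, `snapshots`, `bursts`
#' @export
simulate_network <- function(config, stim, weights = NULL,
                             plasticity = FALSE, seed = 1, trial = 1,
                             snapshot_times_s = numeric(),
                             record_gc = FALSE, record_v = FALSE) {
  stopifnot(inherits(config, "ell_config"), inherits(stim, "stimulus_spec"))
  pars <- build_core_pars(config, stim, stim$duration_s, weights,
                          plasticity, seed, trial, snapshot_times_s,
                          record_gc, record_v)
  res <- sim_network_cpp(pars)
  spikes <- dplyr::bind_rows(
    tibble::tibble(neuron_id = 1L, trial_id = as.integer(trial),
                   spike_time_ms = res$sp1),
    tibble::tibble(neuron_id = 2L, trial_id = as.integer(trial),
                   spike_time_ms = res$sp2)
  )
  out <- list(spikes = spikes, weights = res$weights,
              duration_s = stim$duration_s, f = stim$f,
              geometry = stim$geometry, seed = seed, trial = trial)
  if (!is.null(res$gc)) {
    n_gc <- config$granule$count_per_sp
    out$gc_spikes <- tibble::tibble(
      bank = rep(rep(1:2, each = n_gc), lengths(res$gc)),
      cell = rep(rep(seq_len(n_gc), 2), lengths(res$gc)),
      trial_id = as.integer(trial),
      spike_time_ms = unlist(res$gc, use.names = FALSE) %||% numeric()
    )
  }
  if (!is.null(res$v1)) {
    out$v <- tibble::tibble(
      time_ms = seq_along(res$v1) * config$dt,
      v1 = res$v1, v2 = res$v2
    )
  }
  if (!is.null(res$snapshots)) {
    out$snapshots <- res$snapshots
    out$snapshot_times_s <- snapshot_times_s
  }
  if (!is.null(res$burst_onset1)) {
    out$bursts <- dplyr::bind_rows(
      tibble::tibble(neuron_id = 1L, onset_ms = res$burst_onset1,
                     size = res$burst_size1),
      tibble::tibble(neuron_id = 2L, onset_ms = res$burst_onset2,
                     size = res$burst_size2)
    )
  }
  structure(out, class = "ell_sim")
}

#' Granule-cell stimulus delays
#'
#' The delay of granule cell `i` is `d_i = (i - 1) / (n * f)` so that the
#' delays of a bank of `n` cells tile one stimulus period uniformly: each
#' granule cell responds to its own phase of the sinusoidal stimulus.
#'
#' @param i cell index (1-based), vectorised
#' @param f stimulation frequency (Hz)
#' @param n bank size
#' @return delays in ms
#' @export
granule_delay <- function(i, f, n = 100) {
  if (f <= 0) stop("invalid stimulus: f must be > 0")
  stopifnot(all(i >= 1), all(i <= n))
  1000 * (i - 1) / (n * f)
}

#' Alpha kernel
#'
#' `s(t, a) = (t / a^2) * exp(-t / a)` for `t > 0` and 0 otherwise: the
#' area-normalised alpha function with peak `1 / (a * e)` at `t = a`,
#' used as the DAP time course.
#'
#' @param t time since kernel onset (ms), vectorised
#' @param a time constant (ms)
#' @return kernel values (1/ms)
#' @export
alpha_function <- function(t, a) {
  ifelse(t > 0, (t / a^2) * exp(-t / a), 0)
}

#' Depolarizing afterpotential current
#'
#' Reference implementation of the somato-dendritic DAP: after the
#' somatic spike at `t_n` the current
#' `gamma * alpha * q * s(t - t_n - r_s, tau)` is injected, where
#' `gamma` is the dendro-somatic coupling scale and the amplitude factor
#' `q` is 1 when the dendritic spike succeeds (inter-spike interval
#' longer than the dendritic refractory period at the spike) and is
#' attenuated by `A` on each failure. The dendritic refractory period
#' relaxes toward its baseline `D` with time constant `E` between spikes
#' and grows by the factor `B` at each spike, so trains of short
#' intervals terminate themselves (dendritic burst terminator).
#'
#' @param t evaluation times (ms), vectorised
#' @param spike_times somatic spike times (ms), strictly increasing
#' @param sp [sp_params()]
#' @return DAP current (uA/cm2) at each `t`; 0 before the first spike
#' @export
dap_current <- function(t, spike_times, sp = sp_params()) {
  if (length(spike_times) == 0) return(rep(0, length(t)))
  stopifnot(!is.unsorted(spike_times, strictly = TRUE))
  # evolve the dendritic state across the spike history
  q <- 1
  r_d <- sp$D
  qs <- numeric(length(spike_times))
  for (k in seq_along(spike_times)) {
    if (k > 1) {
      gap <- spike_times[k] - spike_times[k - 1]
      # relaxation of r_d over the interval, then the jump at the spike
      r_d <- sp$D + (r_d - sp$D) * exp(-gap / sp$E)
      success <- gap > r_d
      q <- if (success) 1 else sp$A * q
    }
    qs[k] <- q
    r_d <- sp$B * r_d
  }
  vapply(t, function(tt) {
    k <- findInterval(tt, spike_times)
    if (k == 0) return(0)
    sp$gamma * sp$alpha * qs[k] *
      alpha_function(tt - spike_times[k] - sp$r_s, sp$tau)
  }, numeric(1))
}

#' AMPA conductance of one parallel-fiber synapse
#'
#' `g(t) = g_max * w * sum_k Theta(t - t_k) * exp(-(t - t_k) / tau_AMPA)`:
#' each presynaptic spike at `t_k` adds a step of size `g_max * w` that
#' decays exponentially; contributions superpose linearly.
#'
#' @param t evaluation times (ms), vectorised
#' @param presyn_times presynaptic spike times (ms)
#' @param w synaptic weight in `[0, 1]`
#' @param sp [sp_params()] (for `g_max` and `tau_AMPA`)
#' @return conductance (mS/cm2) at each `t`
#' @export
ampa_conductance <- function(t, presyn_times, w, sp = sp_params()) {
  stopifnot(w >= 0, w <= 1)
  vapply(t, function(tt) {
    dtk <- tt - presyn_times
    sum(sp$g_max * w * exp(-dtk[dtk > 0] / sp$tau_AMPA))
  }, numeric(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
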