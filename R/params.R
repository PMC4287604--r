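#' Superficial pyramidal (SP) cell parameters
#'
#' Membrane, stimulus, synaptic and depolarizing-afterpotential (DAP)
#' constants for the two model SP cells. Defaults are the standard
#' parameter set of the model; units follow the field's conventions
#' (mV, ms, uA/cm2, mS/cm2, uF/cm2).
#'
#' @param C membrane capacitance (uF/cm2)
#' @param g_leak leak conductance (mS/cm2)
#' @param E_leak leak reversal potential (mV)
#' @param I constant bias current (uA/cm2)
#' @param sigma SP noise standard deviation (uA/cm2)
#' @param kappa stimulus amplitude (uA/cm2)
#' @param V_threshold spike threshold (mV)
#' @param V_rest reset / resting potential (mV)
#' @param r_s absolute somatic refractory period (ms)
#' @param g_GABA constant inhibitory conductance (mS/cm2); set to 0 under
#'   local stimulation geometry
#' @param E_GABA inhibitory reversal potential (mV)
#' @param E_AMPA excitatory reversal potential (mV)
#' @param g_max maximal parallel-fiber AMPA conductance (mS/cm2)
#' @param tau_AMPA AMPA conductance decay time constant (ms)
#' @param A attenuation factor applied to the DAP amplitude on each
#'   dendritic spike failure (inter-spike interval shorter than the
#'   dendritic refractory period)
#' @param B growth factor of the dendritic refractory period at each
#'   somatic spike (bursts self-terminate as `r_d` outgrows the
#'   intra-burst interval)
#' @param D,E baseline (ms) and relaxation time constant (ms) of the
#'   dendritic refractory period between spikes
#' @param gamma dendro-somatic coupling scale of the DAP current
#' @param alpha DAP current scale (uA/cm2, applied with `gamma` to the
#'   area-normalised alpha kernel)
#' @param tau DAP alpha-function time constant (ms)
#' @return a list of class `sp_params`
#' @export
sp_params <- function(C = 1, g_leak = 0.14, E_leak = -68.8, I = 0.313,
                      sigma = 0.412, kappa = 0.21, V_threshold = -65,
                      V_rest = -68.8, r_s = 0.7, g_GABA = 0.14,
                      E_GABA = -68.8, E_AMPA = 0, g_max = 0.024,
                      tau_AMPA = 5.26, A = 0.6, B = 2, D = 0.7, E = 24.5,
                      gamma = 0.2, alpha = 10.9, tau = 7) {
  p <- as.list(environment())
  stopifnot(
    C > 0, g_leak >= 0, tau_AMPA > 0, tau > 0, r_s >= 0,
    g_GABA >= 0, g_max >= 0, V_rest <= V_threshold,
    D >= 0, E > 0, sigma >= 0, kappa >= 0
  )
  structure(p, class = "sp_params")
}

#' Granule cell parameters
#'
#' Granule cells use the same integrate-and-fire formalism as the SP
#' cells (same threshold, reset and absolute refractory period) but carry
#' their own noise intensity `rho` and bias `I_gc`, and receive the
#' stimulus through per-cell delays that tile one stimulus period.
#'
#' @param rho granule noise standard deviation (uA/cm2)
#' @param count_per_sp granule cells per SP cell (the two banks are
#'   disjoint)
#' @param I_gc granule bias current (uA/cm2); granule cells rest well
#'   below threshold and are silent without stimulation
#' @param kappa_gc amplitude of the delayed sinusoidal drive each
#'   granule cell receives from the deep-pyramidal relay (uA/cm2). The
#'   default bias/gain pair makes each cell cross threshold only within
#'   a narrow window around its preferred stimulus phase (sharp phase
#'   locking, a couple of spikes per cycle in the deterministic regime),
#'   with `rho`-scale noise perturbing spike timing and count from trial
#'   to trial.
#' @return a list of class `granule_params`
#' @export
granule_params <- function(rho = 0.412, count_per_sp = 100, I_gc = -1.4,
                           kappa_gc = 2) {
  stopifnot(rho >= 0, count_per_sp >= 1, kappa_gc >= 0)
  structure(list(rho = rho, count_per_sp = as.integer(count_per_sp),
                 I_gc = I_gc, kappa_gc = kappa_gc),
            class = "granule_params")
}

#' Burst-timing-dependent plasticity parameters
#'
#' Anti-Hebbian depression triggered by coincident pre/postsynaptic
#' bursts (2-spike and 4-spike classes have their own gain and timing
#' window) plus slow non-associative potentiation toward the upper weight
#' bound.
#'
#' @param eta_2,eta_4 depression per 2-/4-spike burst (dimensionless)
#' @param L_W2,L_W4 total length of the coincidence window for 2-/4-spike
#'   bursts (ms)
#' @param tau_w potentiation time constant (s)
#' @return a list of class `plasticity_params`
#' @export
plasticity_params <- function(eta_2 = 0.0018, eta_4 = 0.0036,
                              L_W2 = 10, L_W4 = 100, tau_w = 4900) {
  stopifnot(eta_2 >= 0, eta_4 >= 0, L_W2 >= 0, L_W4 >= 0, tau_w > 0)
  structure(as.list(environment()), class = "plasticity_params")
}

#' Structured noise parameters
#'
#' The trial-to-trial variability entering the network is built from
#' low-pass filtered (order-4 Butterworth) Gaussian white noise, composed
#' so that the two SP cells share a fraction of their input noise
#' (pairwise correlation `c`) and each granule cell inherits a fraction
#' `e` of its noise from the deep-pyramidal stream of its own column.
#'
#' @param c SP input-noise correlation coefficient, in `[0, 1]`
#' @param e fraction of granule noise shared with the deep-pyramidal/SP
#'   stream, in `[0, 1]`
#' @param cutoff_hz Butterworth low-pass cutoff (Hz)
#' @param order Butterworth filter order
#' @return a list of class `noise_params`
#' @export
noise_params <- function(c = 0.25, e = 1, cutoff_hz = 500, order = 4) {
  stopifnot(c >= 0, c <= 1, e >= 0, e <= 1, cutoff_hz > 0, order >= 1)
  structure(list(c = c, e = e, cutoff_hz = cutoff_hz,
                 order = as.integer(order)),
            class = "noise_params")
}

#' Stimulus specification
#'
#' A sinusoidal amplitude modulation delivered either locally (spatially
#' restricted; parallel-fiber feedback is not recruited, `g_max` and
#' `g_GABA` are set to zero) or globally (spatially diffuse; granule-cell
#' feedback active).
#'
#' @param f stimulation frequency (Hz)
#' @param kappa stimulus amplitude (uA/cm2); defaults to the SP value
#' @param geometry `"local"` or `"global"`
#' @param duration_s stimulus duration (s)
#' @return a list of class `stimulus_spec`
#' @export
stimulus_spec <- function(f = 4, kappa = 0.21,
                          geometry = c("local", "global"), duration_s = 100) {
  geometry <- match.arg(geometry)
  stopifnot(f > 0, duration_s > 0, kappa >= 0)
  structure(list(f = f, kappa = kappa, geometry = geometry,
                 duration_s = duration_s),
            class = "stimulus_spec")
}

#' Protocol specification
#'
#' Trial bookkeeping for the simulated experiments: for global geometry,
#' synaptic weights are first trained to equilibrium, then frozen, and
#' the frozen network is evaluated over repeated trials; local geometry
#' skips training and disconnects the feedback.
#'
#' @param geometry `"local"` or `"global"`
#' @param training_duration_s duration of the plasticity (training) phase
#'   (s); ignored for local geometry
#' @param n_trials number of evaluation trials
#' @param trial_duration_s duration of each trial (s); must hold an
#'   integer number of stimulus cycles
#' @param freeze_weights keep weights fixed during evaluation trials
#' @param seed master seed; every trial consumes an independent substream
#' @return a list of class `protocol_spec`
#' @export
protocol_spec <- function(geometry = c("local", "global"),
                          training_duration_s = 1000, n_trials = 100,
                          trial_duration_s = 100, freeze_weights = TRUE,
                          seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(training_duration_s >= 0, n_trials >= 0, trial_duration_s > 0)
  structure(list(geometry = geometry,
                 training_duration_s = training_duration_s,
                 n_trials = as.integer(n_trials),
                 trial_duration_s = trial_duration_s,
                 freeze_weights = isTRUE(freeze_weights),
                 seed = seed),
            class = "protocol_spec")
}

#' Default model configuration
#'
#' Bundles the default SP, granule, plasticity and noise parameter sets
#' with a stimulus specification, as consumed by [simulate_network()] and
#' [run_protocol()].
#'
#' @param sp [sp_params()]
#' @param granule [granule_params()]
#' @param plasticity [plasticity_params()]
#' @param noise [noise_params()]
#' @param f stimulation frequency (Hz)
#' @param dt integration step (ms)
#' @return a list of class `ell_config`
#' @export
model_config <- function(sp = sp_params(), granule = granule_params(),
                         plasticity = plasticity_params(),
                         noise = noise_params(), f = 4, dt = 0.05) {
  stopifnot(inherits(sp, "sp_params"), inherits(granule, "granule_params"),
            inherits(plasticity, "plasticity_params"),
            inherits(noise, "noise_params"), f > 0, dt > 0)
  structure(list(sp = sp, granule = granule, plasticity = plasticity,
                 noise = noise, f = f, dt = dt),
            class = "ell_config")
}

#' Read / write a model configuration as YAML
#'
#' Configuration files use the printed symbol names (`g_max`, `tau_AMPA`,
#' `c`, `e`, `rho`, `f`, ...) grouped by component, and round-trip
#' losslessly.
#'
#' @param config an `ell_config`
#' @param path file path
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns an `ell_config`.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "ell_config"))
  x <- lapply(config, function(el) if (is.list(el)) unclass(el) else el)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  x <- yaml::read_yaml(path)
  model_config(
    sp = do.call(sp_params, x$sp),
    granule = do.call(granule_params, x$granule),
    plasticity = do.call(plasticity_params, x$plasticity),
    noise = do.call(noise_params, x$noise),
    f = x$f, dt = x$dt
  )
}
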