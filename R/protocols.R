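# Experiment orchestration: training the negative image, frozen-weight
# evaluation over repeated trials, local vs global comparisons and the
# training timecourse.

#' Train the parallel-fiber weights to equilibrium
#'
#' Runs the full network under global stimulation with the plasticity
#' rule active, starting from all weights at 1, and records weight
#' snapshots. The equilibrium weight-vs-phase profile forms a negative
#' image of the stimulus: weights of granule cells firing at the
#' stimulus maximum are depressed the most.
#'
#' @param config a [model_config()]
#' @param f stimulation frequency (Hz); defaults to `config$f`
#' @param duration_s training duration (s)
#' @param snapshot_times_s weight snapshot schedule (s); defaults to the
#'   early-training schedule 0.5..5.5 s every 0.5 s plus a log-spaced
#'   tail and the final time
#' @param seed master seed
#' @return a list of class `ell_training` with the final weights, the
#'   snapshot array, the burst log and the spike table of the training
#'   run
#' @export
train_network <- function(config, f = config$f, duration_s = 1000,
                          snapshot_times_s = NULL, seed = 1) {
  stopifnot(inherits(config, "ell_config"))
  if (is.null(snapshot_times_s)) {
    snapshot_times_s <- unique(sort(c(
      seq(0.5, 5.5, by = 0.5),
      pretty_log_times(duration_s), duration_s
    )))
  }
  snapshot_times_s <- snapshot_times_s[snapshot_times_s <= duration_s]
  stim <- stimulus_spec(f = f, kappa = config$sp$kappa,
                        geometry = "global", duration_s = duration_s)
  sim <- simulate_network(config, stim, weights = NULL, plasticity = TRUE,
                          seed = seed, trial = 0,
                          snapshot_times_s = snapshot_times_s)
  structure(
    list(weights = sim$weights, snapshots = sim$snapshots,
         snapshot_times_s = snapshot_times_s, bursts = sim$bursts,
         spikes = sim$spikes, f = f, duration_s = duration_s,
         config = config, seed = seed),
    class = "ell_training"
  )
}

pretty_log_times <- function(duration_s) {
  out <- 10 * 2^(0:20)
  out[out < duration_s]
}

#' Weight profile versus granule phase
#'
#' @param weights 2 x n weight matrix (or an `ell_training`)
#' @param f stimulation frequency (Hz)
#' @return tibble with `sp_id`, `cell`, `phase` (of the cell's
#'   presynaptic burst, in cycles), `weight`
#' @export
weight_profile <- function(weights, f) {
  if (inherits(weights, "ell_training")) {
    f <- weights$f
    weights <- weights$weights
  }
  n <- ncol(weights)
  ph <- presyn_burst_phase(f, n) / (1000 / f)
  tibble::tibble(
    sp_id = rep(1:2, each = n),
    cell = rep(seq_len(n), 2),
    phase = rep(ph, 2),
    weight = c(t(weights))
  )
}

#' Anti-phase index of a weight profile
#'
#' Circular correlation at zero lag between the equilibrium weight
#' profile (as a function of each granule cell's stimulus phase) and the
#' stimulus sinusoid. A negative value means the profile is a negative
#' image of the stimulus.
#'
#' @inheritParams weight_profile
#' @param sp_id which SP cell's bank (1 or 2)
#' @return correlation between the weights and `sin(2 pi phase)`
#' @export
negative_image_index <- function(weights, f, sp_id = 1) {
  wp <- weight_profile(weights, f)
  wp <- wp[wp$sp_id == sp_id, ]
  if (stats::sd(wp$weight) == 0) return(0)
  stats::cor(wp$weight, sin(2 * pi * wp$phase))
}

#' Run a full simulated stimulation protocol
#'
#' For global geometry: train the weights to equilibrium, freeze them,
#' then evaluate over `n_trials` independent trials. For local geometry:
#' skip training and disconnect the feedback. Every trial consumes an
#' independent noise substream of the master seed; the stimulus phase is
#' zero at every trial start so cycles align across trials.
#'
#' @param spec a [protocol_spec()]
#' @param config a [model_config()]
#' @param f stimulation frequency (Hz)
#' @param weights optional frozen weights (skips training)
#' @return a list of class `ell_protocol` with `spikes` (all trials),
#'   `weights`, `training` (or `NULL`), and the run metadata
#' @export
run_protocol <- function(spec, config = model_config(), f = config$f,
                         weights = NULL) {
  stopifnot(inherits(spec, "protocol_spec"))
  training <- NULL
  if (identical(spec$geometry, "global") && is.null(weights)) {
    training <- train_network(config, f = f,
                              duration_s = spec$training_duration_s,
                              seed = spec$seed)
    weights <- training$weights
  }
  stim <- stimulus_spec(f = f, kappa = config$sp$kappa,
                        geometry = spec$geometry,
                        duration_s = spec$trial_duration_s)
  spikes <- purrr::map_dfr(seq_len(spec$n_trials), function(tr) {
    simulate_network(config, stim, weights = weights, plasticity = FALSE,
                     seed = spec$seed, trial = tr)$spikes
  })
  if (spec$n_trials == 0) {
    spikes <- tibble::tibble(neuron_id = integer(), trial_id = integer(),
                             spike_time_ms = numeric())
  }
  structure(
    list(spikes = spikes, weights = weights, training = training,
         spec = spec, config = config, f = f),
    class = "ell_protocol"
  )
}

#' Local versus global comparison at one parameter point
#'
#' Runs both stimulation geometries with the same configuration and
#' trial schedule and computes the correlation coefficients for each,
#' along with the percentage reduction from local to global.
#'
#' @param config a [model_config()]
#' @param f stimulation frequency (Hz)
#' @param n_trials,trial_duration_s evaluation trial schedule
#' @param training_duration_s training duration for the global arm (s)
#' @param seed master seed
#' @param weights optional pre-trained weights for the global arm
#' @param lag_window_ms lag window for the coefficients
#' @return a list with `coefficients` (tibble, one row per geometry),
#'   `reduction` (tibble of percentage reductions), and both protocol
#'   objects
#' @export
local_global_experiment <- function(config = model_config(), f = config$f,
                                    n_trials = 20, trial_duration_s = 20,
                                    training_duration_s = 300, seed = 1,
                                    weights = NULL,
                                    lag_window_ms = NULL) {
  loc <- run_protocol(
    protocol_spec("local", n_trials = n_trials,
                  trial_duration_s = trial_duration_s, seed = seed),
    config, f = f)
  glo <- run_protocol(
    protocol_spec("global", training_duration_s = training_duration_s,
                  n_trials = n_trials,
                  trial_duration_s = trial_duration_s, seed = seed + 1),
    config, f = f, weights = weights)
  co_l <- correlation_analysis(loc$spikes, f, trial_duration_s,
                               lag_window_ms = lag_window_ms)
  co_g <- correlation_analysis(glo$spikes, f, trial_duration_s,
                               lag_window_ms = lag_window_ms)
  coefficients <- dplyr::bind_rows(
    dplyr::mutate(co_l, geometry = "local", .before = 1),
    dplyr::mutate(co_g, geometry = "global", .before = 1)
  )
  reduction <- tibble::tibble(
    coefficient = c("R_raw", "R_signal", "R_noise"),
    local = c(co_l$R_raw, co_l$R_signal, co_l$R_noise),
    global = c(co_g$R_raw, co_g$R_signal, co_g$R_noise)
  )
  reduction$reduction_pct <- 100 * (reduction$local - reduction$global) /
    reduction$local
  list(coefficients = coefficients, reduction = reduction,
       local = loc, global = glo)
}

#' Frozen-weight evaluations along the training timecourse
#'
#' For each snapshot time, freezes the weights at their value at that
#' time during training and evaluates the frozen network over repeated
#' trials, yielding the timecourse of the correlation coefficients (and
#' of the response modulation) as the negative image forms.
#'
#' @param training an `ell_training` from [train_network()]
#' @param snapshot_times_s which snapshot times to evaluate (s); must be
#'   within the training duration. Time 0 denotes the initial weights
#'   (all 1).
#' @param n_trials,trial_duration_s evaluation schedule per snapshot
#' @param seed master seed for the evaluations
#' @param lag_window_ms lag window for the coefficients
#' @return a tibble: one row per snapshot with the coefficients and the
#'   cycle-histogram modulation depth of SP cell 1
#' @export
run_training_timecourse <- function(training, snapshot_times_s = NULL,
                                    n_trials = 10, trial_duration_s = 10,
                                    seed = 1, lag_window_ms = NULL) {
  stopifnot(inherits(training, "ell_training"))
  if (is.null(snapshot_times_s)) {
    snapshot_times_s <- c(0, training$snapshot_times_s)
  }
  if (any(snapshot_times_s > training$duration_s)) {
    stop("snapshot beyond the training duration")
  }
  config <- training$config
  n_gc <- config$granule$count_per_sp
  purrr::map_dfr(snapshot_times_s, function(ts) {
    w <- snapshot_weights(training, ts)
    prot <- run_protocol(
      protocol_spec("global", n_trials = n_trials,
                    trial_duration_s = trial_duration_s, seed = seed),
      config, f = training$f, weights = w)
    co <- correlation_analysis(prot$spikes, training$f, trial_duration_s,
                               lag_window_ms = lag_window_ms)
    co$time_s <- ts
    co$modulation_hz <- modulation_depth(prot$spikes, 1, training$f,
                                         trial_duration_s)
    co
  })
}

#' Weights at a given time during training
#'
#' @param training an `ell_training`
#' @param time_s snapshot time (s); 0 gives the initial all-1 weights,
#'   other values must match a recorded snapshot
#' @return a 2 x n weight matrix
#' @export
snapshot_weights <- function(training, time_s) {
  n_gc <- training$config$granule$count_per_sp
  if (time_s == 0) return(matrix(1, 2, n_gc))
  idx <- which(abs(training$snapshot_times_s - time_s) < 1e-9)
  if (length(idx) != 1) stop("no snapshot recorded at t = ", time_s, " s")
  matrix(training$snapshots[idx, ], nrow = 2, byrow = TRUE)
}
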