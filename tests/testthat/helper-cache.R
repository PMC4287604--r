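# Shared simulation products for the heavier tests. Everything is
# computed lazily on first use and reused across test files (helpers are
# sourced once per test run). Seeds are fixed so the suite is
# deterministic.
#
# The headline local/global comparison is run with intrinsic granule
# variability (e = 0): the trial-to-trial variability of the granule
# cells must be independent of the pyramidal-cell noise for it to dilute
# the shared input (the regime in which the feedback reduces noise
# correlations; the sweep over e exposes the full dependence).

.ell_cache <- new.env(parent = emptyenv())

cache_get <- function(name, build) {
  if (!exists(name, envir = .ell_cache)) {
    assign(name, build(), envir = .ell_cache)
  }
  get(name, envir = .ell_cache)
}

headline_config <- function() {
  model_config(noise = noise_params(c = 0.25, e = 0))
}

cached_training <- function() {
  cache_get("training", function() {
    train_network(headline_config(), duration_s = 300, seed = 42,
                  snapshot_times_s = c(seq(0.5, 5.5, 0.5), 25, 50, 75,
                                       100, 150, 200, 300))
  })
}

cached_local <- function() {
  cache_get("local", function() {
    run_protocol(
      protocol_spec("local", n_trials = 20, trial_duration_s = 20,
                    seed = 42),
      headline_config())
  })
}

cached_global <- function() {
  cache_get("global", function() {
    run_protocol(
      protocol_spec("global", n_trials = 20, trial_duration_s = 20,
                    seed = 43),
      headline_config(), weights = cached_training()$weights)
  })
}

quick_config <- function(...) model_config(...)
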