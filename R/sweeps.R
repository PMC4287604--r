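# Parameter sweeps contrasting local and global stimulation: granule
# noise intensity rho, the noise-sharing plane (c, e), and the
# (c, stimulation frequency) plane.

sweep_point <- function(config, f, n_trials, trial_duration_s,
                        training_duration_s, seed, lag_window_ms = NULL,
                        geometries = c("local", "global")) {
  purrr::map_dfr(geometries, function(geom) {
    spec <- protocol_spec(geom, training_duration_s = training_duration_s,
                          n_trials = n_trials,
                          trial_duration_s = trial_duration_s, seed = seed)
    prot <- run_protocol(spec, config, f = f)
    co <- correlation_analysis(prot$spikes, f, trial_duration_s,
                               lag_window_ms = lag_window_ms)
    co$geometry <- geom
    co
  })
}

#' Sweep the granule noise intensity rho
#'
#' For each `rho`, computes the correlation coefficients under global
#' stimulation (training, then frozen-weight trials) and under local
#' stimulation, and the global/local ratios. Local-geometry results are
#' invariant to `rho` (the feedback is fully disconnected), so the local
#' baseline is computed once. Uncertainty on the ratios comes from a
#' trial-level bootstrap of each arm.
#'
#' @param rho_grid granule noise SDs to sweep (uA/cm2)
#' @param config base [model_config()]
#' @param f stimulation frequency (Hz)
#' @param n_trials,trial_duration_s evaluation schedule per point
#' @param training_duration_s training duration per point (s)
#' @param seed master seed
#' @param n_boot bootstrap resamples for the ratio CIs (0 to skip)
#' @param lag_window_ms lag window for the coefficients
#' @return a tibble of class `ell_sweep`, one row per grid point, with
#'   the local and global coefficients, their ratios and bootstrap CIs
#' @export
sweep_rho <- function(rho_grid, config = model_config(), f = config$f,
                      n_trials = 10, trial_duration_s = 10,
                      training_duration_s = 150, seed = 1, n_boot = 100,
                      lag_window_ms = NULL) {
  loc_spec <- protocol_spec("local", n_trials = n_trials,
                            trial_duration_s = trial_duration_s,
                            seed = seed)
  loc <- run_protocol(loc_spec, config, f = f)
  co_l <- correlation_analysis(loc$spikes, f, trial_duration_s,
                               lag_window_ms = lag_window_ms)
  out <- purrr::map_dfr(seq_along(rho_grid), function(i) {
    rho <- rho_grid[i]
    cfg <- config
    cfg$granule$rho <- rho
    spec <- protocol_spec("global",
                          training_duration_s = training_duration_s,
                          n_trials = n_trials,
                          trial_duration_s = trial_duration_s,
                          seed = seed + i)
    glo <- run_protocol(spec, cfg, f = f)
    co_g <- correlation_analysis(glo$spikes, f, trial_duration_s,
                                 lag_window_ms = lag_window_ms)
    row <- tibble::tibble(
      rho = rho,
      R_noise_local = co_l$R_noise, R_noise_global = co_g$R_noise,
      R_signal_local = co_l$R_signal, R_signal_global = co_g$R_signal,
      noise_ratio = co_g$R_noise / co_l$R_noise,
      signal_ratio = co_g$R_signal / co_l$R_signal,
      seed = seed + i
    )
    if (n_boot > 0) {
      bg <- bootstrap_coefficients(glo$spikes, f, trial_duration_s,
                                   n_boot = n_boot, seed = seed + i,
                                   lag_window_ms = lag_window_ms)
      bl <- bootstrap_coefficients(loc$spikes, f, trial_duration_s,
                                   n_boot = n_boot, seed = seed + i,
                                   lag_window_ms = lag_window_ms)
      # ratio CI from independent percentile bounds of the two arms
      gn <- bg[bg$coefficient == "R_noise", ]
      ln <- bl[bl$coefficient == "R_noise", ]
      gs <- bg[bg$coefficient == "R_signal", ]
      ls <- bl[bl$coefficient == "R_signal", ]
      row$noise_ratio_low <- gn$conf_low / ln$conf_high
      row$noise_ratio_high <- gn$conf_high / ln$conf_low
      row$signal_ratio_low <- gs$conf_low / ls$conf_high
      row$signal_ratio_high <- gs$conf_high / ls$conf_low
    }
    row
  })
  structure(out, class = c("ell_sweep", class(out)),
            sweep = "rho")
}

#' Sweep the noise-sharing plane (c, e)
#'
#' Noise correlation coefficients under local and global stimulation on
#' a grid of SP input-noise correlation `c` and granule noise-sharing
#' fraction `e`, plus their difference (local - global). The local arm
#' does not depend on `e` and is computed once per `c`.
#'
#' @param c_grid,e_grid grid values in `[0, 1]`
#' @inheritParams sweep_rho
#' @return a tibble of class `ell_sweep`, one row per (c, e) point
#' @export
sweep_c_e <- function(c_grid, e_grid, config = model_config(),
                      f = config$f, n_trials = 10, trial_duration_s = 10,
                      training_duration_s = 150, seed = 1,
                      lag_window_ms = NULL) {
  out <- purrr::map_dfr(seq_along(c_grid), function(ic) {
    cc <- c_grid[ic]
    cfg_l <- config
    cfg_l$noise$c <- cc
    loc <- run_protocol(
      protocol_spec("local", n_trials = n_trials,
                    trial_duration_s = trial_duration_s, seed = seed + ic),
      cfg_l, f = f)
    co_l <- correlation_analysis(loc$spikes, f, trial_duration_s,
                                 lag_window_ms = lag_window_ms)
    purrr::map_dfr(seq_along(e_grid), function(ie) {
      ee <- e_grid[ie]
      cfg <- config
      cfg$noise$c <- cc
      cfg$noise$e <- ee
      glo <- run_protocol(
        protocol_spec("global",
                      training_duration_s = training_duration_s,
                      n_trials = n_trials,
                      trial_duration_s = trial_duration_s,
                      seed = seed + 100 * ic + ie),
        cfg, f = f)
      co_g <- correlation_analysis(glo$spikes, f, trial_duration_s,
                                   lag_window_ms = lag_window_ms)
      tibble::tibble(c = cc, e = ee,
                     R_noise_local = co_l$R_noise,
                     R_noise_global = co_g$R_noise,
                     difference = co_l$R_noise - co_g$R_noise,
                     seed = seed + 100 * ic + ie)
    })
  })
  structure(out, class = c("ell_sweep", class(out)), sweep = "c_e")
}

#' Sweep SP noise correlation against stimulation frequency
#'
#' Noise correlation coefficients under local and global stimulation on
#' a grid of `c` and stimulation frequency `f`, plus their difference.
#'
#' @param c_grid grid of SP input-noise correlations
#' @param f_grid grid of stimulation frequencies (Hz); each must divide
#'   the trial into whole cycles at the analysis binwidth
#' @inheritParams sweep_rho
#' @return a tibble of class `ell_sweep`, one row per (c, f) point
#' @export
sweep_c_f <- function(c_grid, f_grid, config = model_config(),
                      n_trials = 10, trial_duration_s = 10,
                      training_duration_s = 150, seed = 1,
                      lag_window_ms = NULL) {
  out <- purrr::map_dfr(seq_along(c_grid), function(ic) {
    cc <- c_grid[ic]
    purrr::map_dfr(seq_along(f_grid), function(jf) {
      ff <- f_grid[jf]
      cfg <- config
      cfg$noise$c <- cc
      pt <- sweep_point(cfg, ff, n_trials, trial_duration_s,
                        training_duration_s, seed + 100 * ic + jf,
                        lag_window_ms)
      tibble::tibble(
        c = cc, f = ff,
        R_noise_local = pt$R_noise[pt$geometry == "local"],
        R_noise_global = pt$R_noise[pt$geometry == "global"],
        difference = pt$R_noise[pt$geometry == "local"] -
          pt$R_noise[pt$geometry == "global"],
        seed = seed + 100 * ic + jf
      )
    })
  })
  structure(out, class = c("ell_sweep", class(out)), sweep = "c_f")
}
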