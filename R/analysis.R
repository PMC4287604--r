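# Spike-train correlation statistics: binning, auto-/cross-correlograms,
# the shuffle predictor over stimulus cycles, noise correlograms, and the
# scalar signal/noise correlation coefficients derived from them.
#
# Correlogram values are coincidence rates relative to chance, in Hz:
#   C_12(tau) = (1/(N_1 dt)) sum_t X_1(t) X_2(t + tau) - m_2
# with the sum over the spikes of cell 1, N_1 its spike count and m_2 the
# mean rate of cell 2.

#' Bin a spike train
#'
#' Counts spikes in half-open bins `[k dt, (k+1) dt)`.
#'
#' @param spike_times spike times (ms)
#' @param duration_ms recording duration (ms)
#' @param dt_ms binwidth (ms, default 0.5)
#' @return integer vector of per-bin counts; total equals the number of
#'   spikes
#' @export
bin_spikes <- function(spike_times, duration_ms, dt_ms = 0.5) {
  stopifnot(dt_ms > 0, duration_ms > 0)
  if (length(spike_times) &&
      (min(spike_times) < 0 || max(spike_times) >= duration_ms)) {
    stop("spike times must lie in [0, duration)")
  }
  n_bins <- as.integer(round(duration_ms / dt_ms))
  counts <- tabulate(floor(spike_times / dt_ms) + 1L, nbins = n_bins)
  counts
}

# circular FFT cross-correlation of paired columns:
# out[tau+1, k] = sum_b X[b, k] * Y[(b + tau) mod B, k]
circ_xcorr_cols <- function(X, Y) {
  B <- nrow(X)
  Re(stats::mvfft(Conj(stats::mvfft(X)) * stats::mvfft(Y),
                  inverse = TRUE)) / B
}

# linear cross-correlation counts via zero-padded FFT:
# counts[tau] = sum_t x1[t] * x2[t + tau] for tau in -L..L
linear_xcorr <- function(x1, x2, L) {
  n <- length(x1)
  m <- stats::nextn(n + L + 1L, 2)
  f1 <- stats::fft(c(x1, numeric(m - n)))
  f2 <- stats::fft(c(x2, numeric(m - n)))
  cc <- Re(stats::fft(Conj(f1) * f2, inverse = TRUE)) / m
  idx <- c(m + ((-L):(-1)) + 1L, 1L:(L + 1L))
  structure(cc[idx], names = NULL)
}

new_correlogram <- function(lag_ms, value, kind, meta) {
  out <- tibble::tibble(lag_ms = lag_ms, value = value)
  attr(out, "kind") <- kind
  attr(out, "meta") <- meta
  class(out) <- c("ell_correlogram", class(out))
  out
}

#' Auto-correlogram
#'
#' Chance-corrected coincidence rate of a spike train with itself (the
#' zero-lag bin includes the self-coincidence term). Symmetric in the
#' lag.
#'
#' @param spike_times spike times (ms)
#' @param duration_ms recording duration (ms)
#' @param max_lag_ms maximal lag (ms)
#' @param dt_ms binwidth (ms)
#' @return a tibble (`lag_ms`, `value` in Hz) of class `ell_correlogram`
#' @export
acg <- function(spike_times, duration_ms, max_lag_ms = 250, dt_ms = 0.5) {
  if (length(spike_times) == 0) stop("auto-correlogram of an empty train")
  ccg(spike_times, spike_times, duration_ms, max_lag_ms, dt_ms,
      kind = "auto")
}

#' Cross-correlogram
#'
#' Coincidence rate of two simultaneously recorded spike trains relative
#' to chance, as a function of lag; the sum runs over the spikes of
#' train 1, so `C_12(tau) = C_21(-tau)`.
#'
#' @param spike_times1,spike_times2 spike times (ms) of the two trains,
#'   recorded over the same duration
#' @param duration_ms recording duration (ms)
#' @param max_lag_ms maximal lag (ms)
#' @param dt_ms binwidth (ms)
#' @param kind correlogram label
#' @return a tibble (`lag_ms`, `value` in Hz) of class `ell_correlogram`
#' @export
ccg <- function(spike_times1, spike_times2, duration_ms, max_lag_ms = 250,
                dt_ms = 0.5, kind = "cross") {
  x1 <- bin_spikes(spike_times1, duration_ms, dt_ms)
  x2 <- bin_spikes(spike_times2, duration_ms, dt_ms)
  L <- as.integer(round(max_lag_ms / dt_ms))
  counts <- linear_xcorr(x1, x2, L)
  n1 <- length(spike_times1)
  m2 <- length(spike_times2) / (duration_ms / 1000)
  value <- counts / (n1 * dt_ms / 1000) - m2
  new_correlogram(seq(-L, L) * dt_ms, value, kind,
                  meta = list(n1 = n1, n2 = length(spike_times2), m2 = m2,
                              dt_ms = dt_ms, duration_ms = duration_ms))
}

#' Cycle-count matrix
#'
#' Bins one neuron's spikes and splits them into stimulus cycles,
#' pooling cycles across trials (trials are stimulus-phase aligned, so
#' cycle boundaries fall at stimulus phase zero). Trailing partial
#' cycles are discarded.
#'
#' @param spikes tibble with `neuron_id`, `trial_id`, `spike_time_ms`
#' @param neuron neuron id to extract
#' @param f stimulation frequency (Hz)
#' @param trial_duration_s trial duration (s)
#' @param dt_ms binwidth (ms)
#' @return a list with `counts` (bins-per-cycle x n-cycles matrix) and
#'   `trial` (trial id of each cycle column)
#' @export
cycle_counts <- function(spikes, neuron, f, trial_duration_s, dt_ms = 0.5) {
  P <- 1000 / f
  B <- as.integer(round(P / dt_ms))
  if (abs(B * dt_ms - P) > 1e-9) {
    stop("stimulus period must be an integer number of bins")
  }
  dur_ms <- trial_duration_s * 1000
  n_cyc <- floor(dur_ms / P)
  if (n_cyc < 1) stop("trial shorter than one stimulus cycle")
  trials <- sort(unique(spikes$trial_id))
  sub <- spikes[spikes$neuron_id == neuron, ]
  mats <- lapply(trials, function(tr) {
    x <- bin_spikes(sub$spike_time_ms[sub$trial_id == tr], dur_ms, dt_ms)
    matrix(x[seq_len(B * n_cyc)], nrow = B)
  })
  list(counts = do.call(cbind, mats),
       trial = rep(trials, each = n_cyc), B = B, dt_ms = dt_ms, f = f)
}

# core cycle-resolved estimator. X1, X2: bins x cycles count matrices on
# the same cycle grid. Returns within-cycle ("raw"), cross-cycle
# ("shuffle predictor") and their difference ("noise") correlograms with
# circular lags spanning one stimulus period. Cycles without spikes in
# train 1 are excluded from the averaging over cycles of train 1.
cycle_correlogram_engine <- function(X1, X2, dt_ms) {
  B <- nrow(X1)
  M <- ncol(X1)
  stopifnot(nrow(X2) == B, ncol(X2) == M)
  if (M < 2) stop("shuffle predictor requires at least 2 cycles")
  dt_s <- dt_ms / 1000
  P_s <- B * dt_s
  N1k <- colSums(X1)
  m2j <- colSums(X2) / P_s
  valid <- N1k > 0
  Mv <- sum(valid)
  if (Mv == 0) stop("train 1 has no spikes in any cycle")
  U <- sweep(X1, 2, pmax(N1k, 1), "/")
  U[, !valid] <- 0
  S <- circ_xcorr_cols(U, X2)
  W <- rowSums(S[, valid, drop = FALSE])
  tot <- Re(stats::fft(Conj(stats::fft(rowSums(U))) *
                         stats::fft(rowSums(X2)), inverse = TRUE)) / B
  cross <- tot - W
  raw <- W / (Mv * dt_s) - sum(m2j[valid]) / Mv
  shuffle <- cross / (Mv * (M - 1) * dt_s) -
    (Mv * sum(m2j) - sum(m2j[valid])) / (Mv * (M - 1))
  lag_idx <- 0:(B - 1)
  lag <- ifelse(lag_idx > B / 2, lag_idx - B, lag_idx)
  ord <- order(lag)
  list(lag_ms = lag[ord] * dt_ms, raw = raw[ord], shuffle = shuffle[ord],
       noise = raw[ord] - shuffle[ord], M = M, Mv = Mv)
}

#' Shuffle predictor
#'
#' Cross-cycle averaged cross-correlogram: with responses segmented into
#' `M` stimulus cycles, the correlogram between cycle `k` of train 1 and
#' cycle `j` of train 2 is averaged over all ordered pairs `j != k`,
#' with per-cycle normalisation. Because only the stimulus is common
#' across cycles, this estimates the stimulus-locked (signal) component
#' of the correlation.
#'
#' @param cycles1,cycles2 cycle-count matrices from [cycle_counts()]
#'   (bins x cycles) on the same cycle grid
#' @param dt_ms binwidth (ms)
#' @return a tibble (`lag_ms`, `value`) of class `ell_correlogram`
#' @export
shuffle_predictor <- function(cycles1, cycles2, dt_ms = 0.5) {
  eng <- cycle_correlogram_engine(as.matrix(cycles1), as.matrix(cycles2),
                                  dt_ms)
  new_correlogram(eng$lag_ms, eng$shuffle, "shuffle",
                  meta = list(M = eng$M, Mv = eng$Mv, dt_ms = dt_ms))
}

#' Noise cross-correlogram
#'
#' Pointwise difference between a raw correlogram and its shuffle
#' predictor: the correlation attributable to shared trial-to-trial
#' variability. The decomposition `raw = shuffle + noise` holds exactly
#' at every lag.
#'
#' @param raw,shuffle correlograms on identical lags
#' @return a tibble of class `ell_correlogram`
#' @export
noise_ccg <- function(raw, shuffle) {
  if (!isTRUE(all.equal(raw$lag_ms, shuffle$lag_ms))) {
    stop("correlogram lags do not match")
  }
  new_correlogram(raw$lag_ms, raw$value - shuffle$value, "noise",
                  meta = attr(raw, "meta"))
}

#' Cross-correlation coefficient
#'
#' Scalar correlation magnitude: the lag average of the cross-correlogram
#' normalised by the geometric mean of the lag-averaged auto-correlograms,
#' all over the same lag window. Equal to 1 for a train against itself.
#'
#' @param ccg_values cross-correlogram values
#' @param acg1_values,acg2_values auto-correlogram values of the two
#'   trains on the same lags
#' @param lag_ms the common lag axis (ms)
#' @param lag_window_ms half-width of the lag window over which the
#'   average is taken
#' @return the dimensionless coefficient `R`
#' @export
correlation_coefficient <- function(ccg_values, acg1_values, acg2_values,
                                    lag_ms, lag_window_ms) {
  stopifnot(length(ccg_values) == length(lag_ms),
            length(acg1_values) == length(lag_ms),
            length(acg2_values) == length(lag_ms))
  sel <- abs(lag_ms) <= lag_window_ms
  if (!any(sel)) stop("empty lag window")
  den2 <- mean(acg1_values[sel]) * mean(acg2_values[sel])
  if (!is.finite(den2) || den2 <= 0) {
    stop("zero or negative variance in the correlation normalisation")
  }
  mean(ccg_values[sel]) / sqrt(den2)
}

#' Raw, shuffle and noise correlograms for a recorded pair
#'
#' Computes the full cycle-resolved decomposition for neurons 1 and 2 of
#' a spike table: within-cycle (raw) and cross-cycle (shuffle predictor)
#' cross-correlograms, their difference (noise), and the corresponding
#' auto-correlograms of each neuron, on circular lags spanning one
#' stimulus period.
#'
#' @param spikes tibble with `neuron_id`, `trial_id`, `spike_time_ms`
#' @param f stimulation frequency (Hz)
#' @param trial_duration_s trial duration (s)
#' @param dt_ms binwidth (ms)
#' @param neurons the two neuron ids to correlate
#' @return an object of class `ell_correlograms`
#' @export
pair_correlograms <- function(spikes, f, trial_duration_s, dt_ms = 0.5,
                              neurons = c(1L, 2L)) {
  c1 <- cycle_counts(spikes, neurons[1], f, trial_duration_s, dt_ms)
  c2 <- cycle_counts(spikes, neurons[2], f, trial_duration_s, dt_ms)
  pair_correlograms_from_counts(c1$counts, c2$counts, f, dt_ms,
                                trial = c1$trial)
}

pair_correlograms_from_counts <- function(X1, X2, f, dt_ms, trial = NULL) {
  cross <- cycle_correlogram_engine(X1, X2, dt_ms)
  a1 <- cycle_correlogram_engine(X1, X1, dt_ms)
  a2 <- cycle_correlogram_engine(X2, X2, dt_ms)
  structure(
    list(lag_ms = cross$lag_ms,
         cross = tibble::tibble(lag_ms = cross$lag_ms, raw = cross$raw,
                                shuffle = cross$shuffle,
                                noise = cross$noise),
         auto1 = tibble::tibble(lag_ms = a1$lag_ms, raw = a1$raw,
                                shuffle = a1$shuffle, noise = a1$noise),
         auto2 = tibble::tibble(lag_ms = a2$lag_ms, raw = a2$raw,
                                shuffle = a2$shuffle, noise = a2$noise),
         meta = list(f = f, dt_ms = dt_ms, M = cross$M,
                     rate1_hz = sum(X1) / (ncol(X1) / f),
                     rate2_hz = sum(X2) / (ncol(X2) / f),
                     trial = trial)),
    class = "ell_correlograms"
  )
}

#' Signal and noise correlation coefficients
#'
#' Applies the cross-correlation coefficient to the decomposed
#' correlograms of a pair: `R_raw` from the raw correlogram (normalised
#' by the raw auto-correlograms), `R_signal` from the shuffle predictor
#' (normalised by the raw auto-correlograms, so it reflects the
#' stimulus-locked share of the total correlation and shrinks as the
#' response modulation is cancelled), and `R_noise` from the noise
#' correlogram (normalised by the noise auto-correlograms, so fully
#' shared trial-to-trial variability gives exactly 1).
#'
#' @param cg an `ell_correlograms` object from [pair_correlograms()]
#' @param lag_window_ms half-width of the lag average; the default,
#'   `min(P/4, 10)` ms with `P` the stimulus period, is the classical
#'   coincidence window used for correlogram-area correlation measures
#'   (about 1.4 membrane time constants). A window wider than a quarter
#'   period would average the stimulus-locked component toward zero.
#' @return a one-row tibble with `R_raw`, `R_signal`, `R_noise`
#' @export
correlation_coefficients <- function(cg, lag_window_ms = NULL) {
  stopifnot(inherits(cg, "ell_correlograms"))
  if (is.null(lag_window_ms)) lag_window_ms <- min(1000 / cg$meta$f / 4, 10)
  lg <- cg$lag_ms
  tibble::tibble(
    R_raw = correlation_coefficient(cg$cross$raw, cg$auto1$raw,
                                    cg$auto2$raw, lg, lag_window_ms),
    R_signal = correlation_coefficient(cg$cross$shuffle, cg$auto1$raw,
                                       cg$auto2$raw, lg, lag_window_ms),
    R_noise = correlation_coefficient(cg$cross$noise, cg$auto1$noise,
                                      cg$auto2$noise, lg, lag_window_ms),
    lag_window_ms = lag_window_ms
  )
}

#' One-call correlation analysis of a spike table
#'
#' Convenience wrapper: cycle segmentation, correlogram decomposition and
#' the three correlation coefficients for neurons 1 and 2.
#'
#' @inheritParams pair_correlograms
#' @param lag_window_ms lag window for the coefficients (ms)
#' @return a one-row tibble with the coefficients, firing rates and cycle
#'   count
#' @export
correlation_analysis <- function(spikes, f, trial_duration_s, dt_ms = 0.5,
                                 lag_window_ms = NULL,
                                 neurons = c(1L, 2L)) {
  cg <- pair_correlograms(spikes, f, trial_duration_s, dt_ms, neurons)
  co <- correlation_coefficients(cg, lag_window_ms)
  co$rate1_hz <- cg$meta$rate1_hz
  co$rate2_hz <- cg$meta$rate2_hz
  co$n_cycles <- cg$meta$M
  co
}

#' Trial-bootstrap of the correlation coefficients
#'
#' Resamples trials with replacement (keeping all stimulus cycles of each
#' resampled trial) and recomputes the coefficients, giving percentile
#' confidence intervals.
#'
#' @inheritParams correlation_analysis
#' @param n_boot number of bootstrap resamples
#' @param seed RNG seed for the resampling
#' @param conf confidence level
#' @return a tibble with one row per coefficient: estimate and CI bounds
#' @export
bootstrap_coefficients <- function(spikes, f, trial_duration_s,
                                   dt_ms = 0.5, lag_window_ms = NULL,
                                   n_boot = 199, seed = 1, conf = 0.95,
                                   neurons = c(1L, 2L)) {
  c1 <- cycle_counts(spikes, neurons[1], f, trial_duration_s, dt_ms)
  c2 <- cycle_counts(spikes, neurons[2], f, trial_duration_s, dt_ms)
  trials <- unique(c1$trial)
  est <- correlation_coefficients(
    pair_correlograms_from_counts(c1$counts, c2$counts, f, dt_ms),
    lag_window_ms)
  set.seed(seed)
  boot <- replicate(n_boot, {
    pick <- sample(trials, length(trials), replace = TRUE)
    cols <- unlist(lapply(pick, function(tr) which(c1$trial == tr)))
    co <- try(correlation_coefficients(
      pair_correlograms_from_counts(c1$counts[, cols, drop = FALSE],
                                    c2$counts[, cols, drop = FALSE],
                                    f, dt_ms),
      lag_window_ms), silent = TRUE)
    if (inherits(co, "try-error")) c(NA_real_, NA_real_, NA_real_)
    else c(co$R_raw, co$R_signal, co$R_noise)
  })
  alpha <- (1 - conf) / 2
  qs <- apply(boot, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  tibble::tibble(
    coefficient = c("R_raw", "R_signal", "R_noise"),
    estimate = c(est$R_raw, est$R_signal, est$R_noise),
    conf_low = qs[1, ], conf_high = qs[2, ],
    n_boot = n_boot
  )
}

#' Cycle histogram and modulation depth
#'
#' Folds one neuron's spikes over the stimulus period and returns the
#' firing rate per phase bin; `modulation_depth()` is the amplitude of
#' the fundamental Fourier component of that histogram (Hz), the
#' standard measure of how strongly the response is modulated at the
#' stimulus frequency.
#'
#' @param spikes spike table
#' @param neuron neuron id
#' @param f stimulation frequency (Hz)
#' @param trial_duration_s trial duration (s)
#' @param n_bins phase bins per cycle
#' @return `cycle_histogram()`: tibble (`phase`, `rate_hz`);
#'   `modulation_depth()`: scalar Hz
#' @export
cycle_histogram <- function(spikes, neuron, f, trial_duration_s,
                            n_bins = 32) {
  P <- 1000 / f
  sub <- spikes[spikes$neuron_id == neuron, ]
  n_cyc_per_trial <- floor(trial_duration_s * 1000 / P)
  keep <- sub$spike_time_ms < n_cyc_per_trial * P
  ph <- (sub$spike_time_ms[keep] %% P) / P
  counts <- tabulate(pmin(floor(ph * n_bins) + 1L, n_bins), nbins = n_bins)
  n_cyc <- n_cyc_per_trial * length(unique(spikes$trial_id))
  binw_s <- P / n_bins / 1000
  tibble::tibble(phase = (seq_len(n_bins) - 0.5) / n_bins,
                 rate_hz = counts / (n_cyc * binw_s))
}

#' @rdname cycle_histogram
#' @export
modulation_depth <- function(spikes, neuron, f, trial_duration_s,
                             n_bins = 32) {
  h <- cycle_histogram(spikes, neuron, f, trial_duration_s, n_bins)
  2 * Mod(stats::fft(h$rate_hz)[2]) / n_bins
}
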