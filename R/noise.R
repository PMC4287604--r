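#' @useDynLib ellcorr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Butterworth coefficients + the deterministic rescaling factor that
# restores unit variance after causal low-pass filtering of a
# unit-variance white sequence. The factor is 1/sqrt(sum(h^2)) with h the
# filter impulse response; composition weights in the noise model are
# orthonormal, so composed streams stay unit variance.
butter_filter <- function(cutoff_hz, dt_ms, order = 4) {
  fs <- 1000 / dt_ms
  wn <- cutoff_hz / (fs / 2)
  if (wn >= 1) stop("noise filter cutoff must be below the Nyquist frequency")
  bt <- signal::butter(order, wn, type = "low")
  h <- signal::filter(bt, c(1, rep(0, 8191)))
  list(b = as.numeric(bt$b), a = as.numeric(bt$a),
       scale = 1 / sqrt(sum(h^2)))
}

#' Correlated SP input-noise processes
#'
#' Generates the two SP input-noise processes: low-pass filtered
#' (Butterworth) Gaussian white noise with zero mean and unit variance,
#' composed from a shared and two private streams so that their pairwise
#' correlation equals `c`. Filtering is causal (the process drives a
#' stochastic differential equation) and each composed stream is rescaled
#' to unit variance after filtering.
#'
#' @param c pairwise correlation of the two processes, in `[0, 1]`
#' @param n_steps number of samples
#' @param dt_ms sample interval (ms)
#' @param seed master seed; the shared and private streams are
#'   independent named substreams of it
#' @param noise a [noise_params()] (for cutoff and order)
#' @return a tibble with columns `step`, `xi_sp1`, `xi_sp2`
#' @export
make_sp_noise <- function(c, n_steps, dt_ms = 0.05, seed = 1,
                          noise = noise_params(c = c)) {
  stopifnot(c >= 0, c <= 1, n_steps > 0)
  flt <- butter_filter(noise$cutoff_hz, dt_ms, noise$order)
  nb <- noise_bundle_cpp(as.integer(n_steps), c, 0, 0L, 0L, seed, 0,
                         flt$b, flt$a, flt$scale, warmup = 2000L)
  tibble::tibble(step = seq_len(n_steps),
                 xi_sp1 = nb$sp[, 1], xi_sp2 = nb$sp[, 2])
}

#' Granule-cell noise processes
#'
#' Composes per-granule noise from the stream inherited from the
#' deep-pyramidal cells of the cell's own column (identical to the SP
#' input noise of that column) and a private stream, with sharing
#' fraction `e`: `xi_PF = sqrt(e) * xi_SP_j + sqrt(1 - e) * xi_i`.
#'
#' @param c SP input-noise correlation
#' @param e fraction of granule noise inherited from the deep-pyramidal
#'   stream
#' @param n_steps number of samples
#' @param n_gc_out granule cells returned per bank (kept small; the
#'   simulator generates its streams on the fly)
#' @param dt_ms sample interval (ms)
#' @param seed master seed
#' @param noise a [noise_params()]
#' @return a list with matrices `sp` (`n_steps` x 2), `gc1`, `gc2`
#'   (`n_steps` x `n_gc_out`)
#' @export
make_granule_noise <- function(c, e, n_steps, n_gc_out = 4, dt_ms = 0.05,
                               seed = 1, noise = noise_params(c = c, e = e)) {
  stopifnot(c >= 0, c <= 1, e >= 0, e <= 1, n_steps > 0, n_gc_out >= 1)
  flt <- butter_filter(noise$cutoff_hz, dt_ms, noise$order)
  noise_bundle_cpp(as.integer(n_steps), c, e, as.integer(n_gc_out), 100L,
                   seed, 0, flt$b, flt$a, flt$scale, warmup = 2000L)
}
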