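# Binning, correlograms, shuffle predictor, noise decomposition and the
# correlation coefficients, checked against brute-force enumeration and
# hand-computed fixtures.

test_that("binning uses half-open bins and conserves counts", {
  expect_equal(bin_spikes(c(0.1, 0.6), 2, 0.5), c(1, 1, 0, 0))
  expect_equal(bin_spikes(numeric(0), 2, 0.5), rep(0L, 4))
  set.seed(1)
  tt <- runif(1e4, 0, 1000)
  expect_equal(sum(bin_spikes(tt, 1000, 0.5)), 1e4)
  expect_error(bin_spikes(c(-1, 2), 10), "lie in")
  expect_error(bin_spikes(c(1, 10), 10), "lie in")
})

test_that("auto-correlogram is symmetric with peaks at the period", {
  # periodic train: peaks at multiples of the period
  per <- seq(0, 999, by = 50)
  a <- acg(per, 1000, max_lag_ms = 150, dt_ms = 0.5)
  peaks <- a$lag_ms[a$value > max(a$value) / 2]
  expect_true(all(peaks %in% seq(-150, 150, by = 50)))
  expect_equal(a$value, rev(a$value))
  # Poisson train: chance-corrected values near zero off the origin
  set.seed(2)
  pois <- sort(runif(2000, 0, 1e5))
  ap <- acg(pois, 1e5, 50, 0.5)
  expect_lt(mean(abs(ap$value[ap$lag_ms != 0])), 6)
  expect_error(acg(numeric(0), 100), "empty")
})

test_that("cross-correlogram matches brute-force pair counting", {
  set.seed(3)
  for (i in 1:25) {
    n1 <- sample(5:200, 1); n2 <- sample(5:200, 1)
    t1 <- random_train(n1, 2000); t2 <- random_train(n2, 2000)
    got <- ccg(t1, t2, 2000, max_lag_ms = 40, dt_ms = 0.5)
    expect_equal(got$value, oracle_ccg(t1, t2, 2000, 40, 0.5),
                 tolerance = 1e-8)
  }
  # identity and reflection properties
  t1 <- random_train(80, 1000)
  t2 <- random_train(60, 1000)
  expect_equal(ccg(t1, t1, 1000, 30)$value, acg(t1, 1000, 30)$value)
  c12 <- ccg(t1, t2, 1000, 30)
  c21 <- ccg(t2, t1, 1000, 30)
  # C_12(tau) * N1 = C_21(-tau) * N2 up to the chance terms; check via
  # raw coincidence counts
  cnt12 <- (c12$value + length(t2) / 1) * length(t1) * 5e-4
  cnt21 <- (c21$value + length(t1) / 1) * length(t2) * 5e-4
  expect_equal(cnt12, rev(cnt21), tolerance = 1e-8)
  expect_error(ccg(c(0.1), c(5), 10, max_lag_ms = 3, dt_ms = 0.5), NA)
})

test_that("cycle-resolved raw and shuffle correlograms match enumeration", {
  set.seed(4)
  for (i in 1:20) {
    B <- sample(c(8, 10, 16), 1)
    M <- sample(2:6, 1)
    X1 <- matrix(rpois(B * M, 0.5), B, M)
    X2 <- matrix(rpois(B * M, 0.5), B, M)
    if (all(colSums(X1) == 0)) X1[1, 1] <- 1
    eng <- ellcorr:::cycle_correlogram_engine(X1, X2, dt_ms = 2)
    ora <- oracle_cycle(X1, X2, dt_ms = 2)
    expect_equal(eng$raw, ora$raw, tolerance = 1e-9)
    expect_equal(eng$shuffle, ora$shuffle, tolerance = 1e-9)
    # decomposition identity holds exactly at every lag
    expect_equal(eng$noise, eng$raw - eng$shuffle)
  }
})

test_that("known-answer fixture reproduces the hand-enumerated values", {
  fx <- known_answer_fixture()
  cg <- pair_correlograms(fx$spikes, fx$f, fx$trial_duration_s, fx$dt_ms)
  ref <- rep(-15, 10)
  names(ref) <- as.character(seq(-40, 50, by = 10))
  raw <- ref; raw[c("0", "-30")] <- 35; raw[c("20", "50")] <- 10
  shf <- ref; shf[c("0", "-30")] <- 35; shf[c("40", "50")] <- 10
  expect_equal(cg$lag_ms, seq(-40, 50, by = 10))
  expect_equal(cg$cross$raw, unname(raw))
  expect_equal(cg$cross$shuffle, unname(shf))
  nz <- rep(0, 10); nz[match(c(20, 40), cg$lag_ms)] <- c(25, -25)
  expect_equal(cg$cross$noise, nz, tolerance = 1e-9)
})

test_that("identical cycles yield a zero noise correlogram", {
  one <- c(1, 0, 0, 2, 0, 0, 1, 0)
  X <- matrix(rep(one, 4), 8, 4)
  eng <- ellcorr:::cycle_correlogram_engine(X, X, dt_ms = 1)
  expect_equal(eng$noise, rep(0, 8), tolerance = 1e-9)
  expect_equal(eng$raw, eng$shuffle, tolerance = 1e-9)
})

test_that("noise_ccg subtracts pointwise and rejects mismatched lags", {
  t1 <- random_train(50, 1000); t2 <- random_train(40, 1000)
  raw <- ccg(t1, t2, 1000, 20)
  shf <- ccg(t1, t2, 1000, 20)
  nz <- noise_ccg(raw, shf)
  expect_equal(nz$value, rep(0, nrow(raw)))
  bad <- ccg(t1, t2, 1000, 30)
  expect_error(noise_ccg(raw, bad), "lags")
})

test_that("correlation coefficient normalises to 1 for a train with itself", {
  set.seed(6)
  spikes <- dplyr::bind_rows(
    tibble::tibble(neuron_id = 1L, trial_id = 1L,
                   spike_time_ms = sort(runif(400, 0, 1e4))),
    tibble::tibble(neuron_id = 2L, trial_id = 1L,
                   spike_time_ms = sort(runif(300, 0, 1e4)))
  )
  twin <- dplyr::bind_rows(
    spikes[spikes$neuron_id == 1, ],
    dplyr::mutate(spikes[spikes$neuron_id == 1, ], neuron_id = 2L)
  )
  co <- correlation_analysis(twin, f = 4, trial_duration_s = 10)
  expect_equal(co$R_raw, 1, tolerance = 1e-9)
  expect_equal(co$R_noise, 1, tolerance = 1e-9)
  # independent long Poisson trains: all coefficients near zero
  long <- dplyr::bind_rows(
    tibble::tibble(neuron_id = 1L, trial_id = 1L,
                   spike_time_ms = sort(runif(4000, 0, 1e5))),
    tibble::tibble(neuron_id = 2L, trial_id = 1L,
                   spike_time_ms = sort(runif(3000, 0, 1e5)))
  )
  co0 <- correlation_analysis(long, f = 4, trial_duration_s = 100)
  expect_lt(abs(co0$R_raw), 0.05)
  expect_lt(abs(co0$R_noise), 0.05)
  # degenerate: empty lag window / zero variance signalled
  expect_error(correlation_coefficient(1:5, rep(0, 5), rep(0, 5),
                                       seq(-2, 2), 2), "variance")
})

test_that("cycle-shuffled surrogates reproduce the shuffle predictor", {
  sp <- surrogate_spec(m_sig = 0.6, m_noise = 0.4, n_trials = 12,
                       trial_duration_s = 10, seed = 31)
  spikes <- generate_pair(sp)
  c1 <- cycle_counts(spikes, 1, 4, 10)
  c2 <- cycle_counts(spikes, 2, 4, 10)
  eng <- ellcorr:::cycle_correlogram_engine(c1$counts, c2$counts, 0.5)
  # derangement of the cycles of neuron 2 breaks within-cycle noise
  # correlations; the raw correlogram of the shuffled pair estimates the
  # shuffle predictor of the original
  # map every cycle into a different trial so the trial-wise shared
  # noise is broken (173 is coprime to the 40 cycles per trial)
  M <- ncol(c2$counts)
  perm <- ((seq_len(M) - 1 + 173) %% M) + 1
  eng_p <- ellcorr:::cycle_correlogram_engine(c1$counts,
                                              c2$counts[, perm], 0.5)
  # the single-pairing estimate is bin-wise noisy; compare the smoothed
  # correlograms (10 ms circular boxcar)
  sm <- function(x) as.numeric(stats::filter(x, rep(1 / 21, 21),
                                             circular = TRUE))
  expect_gt(stats::cor(sm(eng_p$raw), sm(eng$shuffle)), 0.85)
  expect_lt(mean(abs(sm(eng_p$raw) - sm(eng$shuffle))),
            stats::sd(eng$shuffle))
})

test_that("cycle histogram and modulation depth recover a known modulation", {
  # inhomogeneous Poisson with known rate modulation
  set.seed(8)
  dt <- 0.5
  tt <- seq(0, 20e3 - dt, by = dt)
  lam <- 30 * (1 + 0.5 * sin(2 * pi * 4 * tt / 1000))
  counts <- rpois(length(tt), lam * dt / 1000)
  spikes <- tibble::tibble(neuron_id = 1L, trial_id = 1L,
                           spike_time_ms = rep(tt, counts))
  h <- cycle_histogram(spikes, 1, 4, 20)
  expect_equal(mean(h$rate_hz), 30, tolerance = 0.1)
  expect_equal(modulation_depth(spikes, 1, 4, 20), 15, tolerance = 0.15)
})
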