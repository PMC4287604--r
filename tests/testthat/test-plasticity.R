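# Burst classification (exclusive assignment, 4-spike priority) and the
# depression/potentiation weight dynamics.

test_that("burst classification handles the canonical patterns", {
  # four spikes spanning 44 ms -> one 4-spike burst
  b <- classify_bursts(c(0, 14, 28, 44))
  expect_equal(nrow(b), 1)
  expect_equal(b$size, 4L)
  expect_equal(b$onset_ms, 0)
  expect_equal(b$members[[1]], 1:4)
  # an early close pair is classified once it is 4th-most-recent
  b2 <- classify_bursts(c(0, 12, 200, 400, 600))
  expect_equal(nrow(b2), 1)
  expect_equal(b2$size, 2L)
  expect_equal(b2$onset_ms, 0)
  expect_equal(b2$members[[1]], 1:2)
  # evenly spaced 20 ms train: no pair within 15, no quadruple within 45
  expect_equal(nrow(classify_bursts(c(0, 20, 40, 60))), 0)
  expect_error(classify_bursts(c(5, 3)), "increasing")
})

test_that("online classification matches the sequential oracle with
           exclusivity and 4-spike priority", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    times <- sort(cumsum(runif(n, 0.8, 30)))
    got <- classify_bursts(times)
    ora <- oracle_bursts(times)
    expect_equal(got$onset_ms, ora$onset)
    expect_equal(got$size, as.integer(ora$size))
    # exclusivity: no spike in two bursts; burst sizes match membership
    mem <- unlist(got$members)
    expect_equal(anyDuplicated(mem), 0)
    expect_equal(lengths(got$members), as.integer(got$size))
  }
})

test_that("depression is windowed, multiplicative and class-scaled", {
  pl <- plasticity_params()
  n <- 100
  w <- rep(0.8, n)
  tpre <- presyn_burst_phase(4, n)
  # a burst whose window covers no presynaptic phase leaves weights alone
  w2 <- depress_weights(w, burst_onset_ms = tpre[1] + 100, burst_size = 2,
                        f = 4, plasticity = pl)
  expect_true(all(w2[abs((tpre - (tpre[1] + 100) + 125) %% 250 - 125) >
                       pl$L_W2 / 2] == 0.8))
  # in-window weights are scaled by (1 - eta); 4-spike gain is twice the
  # 2-spike gain for the same timing
  on <- tpre[10]
  w4 <- depress_weights(w, on, 4, 4, pl)
  w2b <- depress_weights(w, on, 2, 4, pl)
  expect_equal(1 - w4[10] / 0.8, 2 * (1 - w2b[10] / 0.8), tolerance = 1e-12)
  expect_equal(w4[10], 0.8 * (1 - pl$eta_4))
  # box kernel: inside/outside the half-window
  expect_equal(btdp_kernel(c(-60, -49, 0, 49, 60), 100),
               c(0, 1, 1, 1, 0))
})

test_that("potentiation relaxes to the upper bound with tau_w", {
  pl <- plasticity_params()
  # fixed point
  expect_equal(potentiate_weights(1, 100, pl), 1)
  # closed form against numerical ODE integration over 100 s
  w0 <- 0.3
  euler <- w0
  dt <- 0.001
  for (i in seq_len(1e5)) euler <- euler + dt * (1 - euler) / pl$tau_w
  expect_equal(potentiate_weights(w0, 100, pl), euler, tolerance = 1e-6)
  # monotone: never drives a weight below its initial value
  expect_true(all(potentiate_weights(seq(0, 1, 0.1), 50, pl) >=
                    seq(0, 1, 0.1)))
})

test_that("training forms an anti-phase (negative image) weight profile", {
  cfg <- headline_config()
  tr <- cached_training()
  expect_true(all(tr$weights >= 0 & tr$weights <= 1))
  expect_true(all(tr$snapshots >= 0 & tr$snapshots <= 1))
  expect_lt(negative_image_index(tr, tr$f, sp_id = 1), -0.5)
  expect_lt(negative_image_index(tr, tr$f, sp_id = 2), -0.5)
  # both burst classes occur during training
  expect_setequal(unique(tr$bursts$size), c(2L, 4L))
})

test_that("with plasticity gains zero, weights only drift toward one", {
  cfg <- model_config(plasticity = plasticity_params(eta_2 = 0, eta_4 = 0,
                                                     tau_w = 50))
  tr <- train_network(cfg, duration_s = 20, seed = 3,
                      snapshot_times_s = c(10, 20))
  expect_true(all(tr$weights == 1))  # starts at the fixed point, stays
  cfg2 <- cfg
  w0 <- matrix(0.5, 2, 100)
  stim <- stimulus_spec(geometry = "global", duration_s = 20)
  sim <- simulate_network(cfg2, stim, weights = w0, plasticity = TRUE,
                          seed = 3)
  expect_true(all(sim$weights > 0.5))
  expect_lt(max(abs(sim$weights - potentiate_weights(0.5, 20, cfg$plasticity))),
            1e-6)
})
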