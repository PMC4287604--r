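# Protocol orchestration: determinism, trial bookkeeping, geometry
# switches and the invariances they imply.

test_that("identical master seeds reproduce a whole protocol", {
  spec <- protocol_spec("local", n_trials = 2, trial_duration_s = 5,
                        seed = 7)
  a <- run_protocol(spec, model_config())
  b <- run_protocol(spec, model_config())
  expect_identical(a$spikes, b$spikes)
  expect_equal(sort(unique(a$spikes$trial_id)), 1:2)
})

test_that("zero trials give an empty but well-formed result", {
  spec <- protocol_spec("local", n_trials = 0, trial_duration_s = 5,
                        seed = 1)
  pr <- run_protocol(spec, model_config())
  expect_equal(nrow(pr$spikes), 0)
  expect_named(pr$spikes, c("neuron_id", "trial_id", "spike_time_ms"))
  expect_s3_class(pr$spec, "protocol_spec")
})

test_that("local runs are invariant to granule and plasticity parameters", {
  spec <- protocol_spec("local", n_trials = 1, trial_duration_s = 5,
                        seed = 5)
  base <- run_protocol(spec, model_config())
  alt <- run_protocol(spec, model_config(
    granule = granule_params(rho = 3),
    noise = noise_params(c = 0.25, e = 0.1),
    plasticity = plasticity_params(eta_2 = 1, eta_4 = 1)))
  expect_identical(base$spikes, alt$spikes)
})

test_that("pooled statistics are invariant to trial relabelling", {
  spec <- protocol_spec("local", n_trials = 4, trial_duration_s = 5,
                        seed = 11)
  pr <- run_protocol(spec, model_config())
  co <- correlation_analysis(pr$spikes, 4, 5)
  shuffled <- pr$spikes
  map <- stats::setNames(c(3L, 1L, 4L, 2L), 1:4)
  shuffled$trial_id <- map[as.character(shuffled$trial_id)]
  co2 <- correlation_analysis(shuffled, 4, 5)
  expect_equal(co$R_raw, co2$R_raw, tolerance = 1e-12)
  expect_equal(co$R_noise, co2$R_noise, tolerance = 1e-12)
})

test_that("training snapshots freeze and reload correctly", {
  tr <- cached_training()
  w25 <- snapshot_weights(tr, 25)
  expect_equal(dim(w25), c(2, 100))
  expect_true(all(w25 >= 0 & w25 <= 1))
  expect_equal(snapshot_weights(tr, 0), matrix(1, 2, 100))
  expect_error(snapshot_weights(tr, 123.456), "no snapshot")
  expect_error(
    run_training_timecourse(tr, snapshot_times_s = tr$duration_s + 10),
    "beyond")
})

test_that("global protocol trains, freezes and evaluates", {
  cfg <- headline_config()
  glo <- cached_global()
  expect_equal(glo$weights, cached_training()$weights)
  expect_equal(length(unique(glo$spikes$trial_id)), 20)
  # frozen weights: evaluation does not alter them
  expect_true(all(glo$weights >= 0 & glo$weights <= 1))
})
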