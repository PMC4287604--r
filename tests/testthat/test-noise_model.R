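# Structured low-pass-filtered noise: unit variance, prescribed
# correlations, substream reproducibility and causal prefix property.

test_that("filtered noise has zero mean, unit variance and correlation c", {
  n <- 4e5
  for (cc in c(0, 0.25, 1)) {
    ns <- make_sp_noise(cc, n, seed = 11)
    expect_lt(abs(mean(ns$xi_sp1)), 0.02)
    expect_lt(abs(var(ns$xi_sp1) - 1), 0.03)
    expect_lt(abs(var(ns$xi_sp2) - 1), 0.03)
    expect_lt(abs(cor(ns$xi_sp1, ns$xi_sp2) - cc), 0.03)
  }
  # fully shared noise is the identical sample path
  ns1 <- make_sp_noise(1, 1e4, seed = 3)
  expect_identical(ns1$xi_sp1, ns1$xi_sp2)
})

test_that("granule noise composition follows the sharing structure", {
  n <- 2e5
  # e = 0: granule streams independent of each other and of the SP noise
  nb0 <- make_granule_noise(c = 0.25, e = 0, n, n_gc_out = 2, seed = 5)
  expect_lt(abs(cor(nb0$gc1[, 1], nb0$gc1[, 2])), 0.03)
  expect_lt(abs(cor(nb0$gc1[, 1], nb0$sp[, 1])), 0.03)
  expect_lt(abs(cor(nb0$gc1[, 1], nb0$gc2[, 1])), 0.03)
  # e = 1, c = 1: every granule stream equals the single shared SP noise
  nb1 <- make_granule_noise(c = 1, e = 1, n_steps = 1e4, n_gc_out = 2,
                            seed = 5)
  expect_equal(nb1$gc1[, 1], nb1$sp[, 1])
  expect_equal(nb1$gc2[, 2], nb1$sp[, 2])
  expect_equal(nb1$gc1[, 1], nb1$gc2[, 1])
  # e = 1, c = 0.25: cross-bank granule correlation equals the analytic
  # composition value c (granule noise is the bank's SP stream itself)
  nb <- make_granule_noise(c = 0.25, e = 1, n, n_gc_out = 1, seed = 7)
  expect_lt(abs(cor(nb$gc1[, 1], nb$gc2[, 1]) - 0.25), 0.03)
  # within-bank correlation at intermediate e: sqrt(e)^2 = e
  nbe <- make_granule_noise(c = 0.25, e = 0.5, n, n_gc_out = 2, seed = 9)
  expect_lt(abs(cor(nbe$gc1[, 1], nbe$gc1[, 2]) - 0.5), 0.03)
})

test_that("noise streams are reproducible and causal", {
  a <- make_sp_noise(0.25, 2000, seed = 21)
  b <- make_sp_noise(0.25, 2000, seed = 21)
  expect_identical(a, b)
  # prefix property: output up to step k does not depend on later draws
  short <- make_sp_noise(0.25, 500, seed = 21)
  expect_equal(short$xi_sp1, a$xi_sp1[1:500])
  # different seeds give different paths
  d <- make_sp_noise(0.25, 2000, seed = 22)
  expect_gt(max(abs(d$xi_sp1 - a$xi_sp1)), 0.1)
})

test_that("correlation structure is invariant to the seed", {
  cors <- vapply(1:8, function(s) {
    ns <- make_sp_noise(0.25, 5e4, seed = s)
    cor(ns$xi_sp1, ns$xi_sp2)
  }, numeric(1))
  expect_lt(max(abs(cors - 0.25)), 0.06)
  expect_lt(abs(mean(cors) - 0.25), 0.02)
})
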