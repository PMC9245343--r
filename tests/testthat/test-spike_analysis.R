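test_that("baseline subtraction removes offsets and estimates noise", {
  t <- seq(0, 10e-3, 1e-4)
  ## constant trace: zeros, zero SD
  flat <- tibble::tibble(time = t, current = rep(3e-12, length(t)))
  s <- baseline_subtract(flat, pre_end = 5e-3)
  expect_true(all(s$current == 0))
  expect_equal(attr(s, "baseline_sd"), 0)
  ## additive offset is removed exactly
  spike_part <- ifelse(t > 5e-3, 1e-11 * exp(-(t - 5e-3) / 1e-3), 0)
  off <- tibble::tibble(time = t, current = spike_part + 5e-12)
  s2 <- baseline_subtract(off, pre_end = 5e-3)
  expect_equal(s2$current, spike_part[t > 5e-3])
  ## noisy baseline SD close to the injected SD (long window, fixed seed)
  set.seed(3)
  t3 <- seq(0, 60e-3, 1e-4)
  noisy <- tibble::tibble(
    time = t3,
    current = 5e-12 + rnorm(length(t3), 0, 1e-13) +
      ifelse(t3 > 50e-3, 1e-11, 0)
  )
  s3 <- baseline_subtract(noisy, pre_end = 50e-3)
  expect_equal(attr(s3, "baseline_sd"), 1e-13, tolerance = 0.2)
  expect_error(baseline_subtract(flat, pre_end = -1), class = "poretrace_validation_error")
})

test_that("spike features: ramp rise time, apex, charge", {
  ## linear ramp 0 -> I_max over 1 ms then instant drop: t_rise = 0.9 ms
  t <- seq(0, 1.2e-3, 1e-5)
  I <- ifelse(t <= 1e-3, 1e-11 * t / 1e-3, 0)
  f <- spike_features(as_spike(t, I))
  expect_equal(f$t_rise, 0.9e-3, tolerance = 1e-6)
  expect_equal(f$i_max, 1e-11)
  ## symmetric triangle peaks at the apex sample
  t2 <- seq(0, 2e-3, 1e-4)
  tri <- 1e-11 * (1 - abs(t2 - 1e-3) / 1e-3)
  f2 <- spike_features(as_spike(t2, tri))
  expect_equal(f2$t_max, 1e-3)
  ## t_rise is invariant to uniform current rescaling
  f3 <- spike_features(as_spike(t, I * 7))
  expect_equal(f3$t_rise, f$t_rise)
})

test_that("t_rise matches a 10x oversampled re-simulation within one sample", {
  geom <- std_geometry()
  q <- 0.5e-12
  c0 <- initial_concentration(q, geom$vesicle_radius)
  trp <- transport_params()
  lt <- logistic_trajectory(15e-9, 1e-3, 0.3e-3, 3e-3, dt = 1e-5)
  coarse <- quasi_steady_current(geom, trp, c0, lt, 3e-3, dt_output = 1e-4)
  fine <- quasi_steady_current(geom, trp, c0, lt, 3e-3, dt_output = 1e-5)
  r1 <- spike_features(as_spike(coarse$time, coarse$current))$t_rise
  r2 <- spike_features(as_spike(fine$time, fine$current))$t_rise
  expect_lt(abs(r1 - r2), 1e-4)
})

test_that("spike charge equals the generating trace integral", {
  geom <- std_geometry()
  q <- 0.5e-12
  lt <- logistic_trajectory(20e-9, 0.8e-3, 0.25e-3, 3e-3)
  syn <- synth_spike(lt, q, geom, noise_sd_frac = 0, backend = "quasi-steady")
  expect_equal(
    spike_features(syn$spike)$q,
    released_charge(syn$trace)
  )
})

test_that("decay classification separates single from double exponentials", {
  t <- seq(0, 20e-3, 1e-4)
  ## exact single exponential
  s1 <- as_spike(t, 1e-11 * exp(-t / 1e-3))
  d1 <- classify_decay(s1)
  expect_equal(d1$tau, 1e-3, tolerance = 0.01)
  expect_gte(d1$r_squared, 0.999)
  expect_true(d1$nondense_core)
  ## equal-weight sum of tau = 0.3 / 3 ms is rejected at threshold 0.98
  s2 <- as_spike(t, 5e-12 * (exp(-t / 0.3e-3) + exp(-t / 3e-3)))
  d2 <- classify_decay(s2, r2_threshold = 0.98)
  expect_lt(d2$r_squared, 0.98)
  expect_false(d2$nondense_core)
  ## 1% noise keeps a true exponential classified at threshold 0.95
  set.seed(7)
  s3 <- as_spike(t, 1e-11 * exp(-t / 1e-3) + rnorm(length(t), 0, 1e-13))
  d3 <- classify_decay(s3, r2_threshold = 0.95)
  expect_true(d3$nondense_core)
})

test_that("current rise time tracks the trajectory expansion time", {
  geom <- std_geometry()
  q <- 0.3e-12 # modest content: limited depletion during expansion
  c0 <- initial_concentration(q, geom$vesicle_radius)
  lt <- logistic_trajectory(15e-9, 1e-3, 0.3e-3, 3e-3)
  tr <- quasi_steady_current(geom, transport_params(), c0, lt, 3e-3)
  t_rise <- spike_features(as_spike(tr$time, tr$current))$t_rise
  t_expa <- pore_features(lt)$t_expa
  expect_equal(t_rise, t_expa, tolerance = 0.30)
})
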