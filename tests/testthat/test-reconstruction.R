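test_that("fit_step honours fixed points, bounds, and the noise floor", {
  geom <- std_geometry()
  q <- 0.5e-12
  st <- fesa_init(geom, transport_params(), q, recon_config())
  st <- advance_fesa(st, 5e-9, 1e-4)
  target <- advance_fesa(st, 5e-9, 1e-4)$I
  ## fixed point: target produced by holding the previous radius
  fx <- fit_step(st, target, span = 1e-4)
  expect_equal(fx$radius, 5e-9, tolerance = 1e-2)
  expect_identical(fx$flag, "ok")
  ## unreachable target clips at the upper bound
  cl <- fit_step(st, 1e-6, span = 1e-4)
  expect_equal(cl$radius, 0.8 * geom$vesicle_radius)
  expect_identical(cl$flag, "clipped")
  ## target under the noise floor keeps the previous radius
  un <- fit_step(st, 1e-14, noise_floor = 1e-13, span = 1e-4)
  expect_equal(un$radius, 5e-9)
  expect_identical(un$flag, "unidentifiable")
})

test_that("a single forward-simulated step is inverted to the known knot", {
  geom <- std_geometry()
  st <- fesa_init(geom, transport_params(), 0.5e-12, recon_config())
  st <- advance_fesa(st, 4e-9, 1e-4)
  truth <- 7e-9
  target <- advance_fesa(st, truth, 1e-4)$I
  fs <- fit_step(st, target, span = 1e-4)
  expect_equal(fs$radius, truth, tolerance = max(0.02, 1e-11 / truth))
})

test_that("noiseless closed-loop recovery stays within 5% across sizes", {
  for (rves in c(75e-9, 150e-9, 300e-9)) {
    for (frac in c(0.05, 0.1, 0.3)) {
      geom <- std_geometry(rves)
      q <- 0.5e-12
      lt <- logistic_trajectory(frac * rves, 1e-3, 0.3e-3, 4e-3)
      syn <- synth_spike(lt, q, geom, noise_sd_frac = 0, backend = "quasi-steady")
      fit <- reconstruct_pore_trajectory(syn$spike, rves, q = q)
      truth <- pore_radius_at(lt, fit$trajectory$time)
      win <- c(FALSE, tidy(fit)$released_fraction < 0.90)
      rel <- abs(fit$trajectory$radius - truth) / truth
      expect_lt(max(rel[win]), 0.05)
    }
  }
})

test_that("2% noise leaves R_p,max within 10% and t_expa within 20%", {
  geom <- std_geometry()
  q <- 0.5e-12
  lt <- logistic_trajectory(30e-9, 1e-3, 0.3e-3, 4e-3)
  syn <- synth_spike(lt, q, geom, noise_sd_frac = 0.02, seed = 42, backend = "quasi-steady")
  fit <- reconstruct_pore_trajectory(syn$spike, geom$vesicle_radius, q = q)
  truth <- pore_features(lt)
  expect_equal(fit$r_p_max, truth$r_p_max, tolerance = 0.10)
  expect_equal(fit$t_expa, truth$t_expa, tolerance = 0.20)
})

test_that("a flat zero spike yields no identifiable radii", {
  sp <- as_spike(seq(0, 2e-3, 1e-4), rep(0, 21), baseline_sd = 1e-14)
  fit <- reconstruct_pore_trajectory(sp, 150e-9, q = 1e-13)
  expect_true(all(tidy(fit)$flag == "unidentifiable"))
  expect_true(all(tidy(fit)$radius <= 1e-10))
})

test_that("reconstruction is deterministic and causally sequential", {
  geom <- std_geometry()
  q <- 0.5e-12
  lt <- logistic_trajectory(15e-9, 1e-3, 0.3e-3, 3e-3)
  syn <- synth_spike(lt, q, geom, noise_sd_frac = 0.02, seed = 5, backend = "quasi-steady")
  f1 <- reconstruct_pore_trajectory(syn$spike, geom$vesicle_radius, q = q)
  f2 <- reconstruct_pore_trajectory(syn$spike, geom$vesicle_radius, q = q)
  expect_identical(f1$trajectory$radius, f2$trajectory$radius)
  ## truncated spike reproduces the common prefix exactly
  short <- as_spike(syn$spike$time[1:20], syn$spike$current[1:20],
    baseline_sd = attr(syn$spike, "baseline_sd")
  )
  f3 <- reconstruct_pore_trajectory(short, geom$vesicle_radius, q = q)
  expect_identical(f3$trajectory$radius, f1$trajectory$radius[1:20])
})

test_that("residuals at unflagged steps are small against the target scale", {
  geom <- std_geometry()
  q <- 0.5e-12
  lt <- logistic_trajectory(20e-9, 1e-3, 0.3e-3, 3e-3)
  syn <- synth_spike(lt, q, geom, noise_sd_frac = 0, backend = "quasi-steady")
  fit <- reconstruct_pore_trajectory(syn$spike, geom$vesicle_radius, q = q)
  st <- tidy(fit)
  ok <- st$flag == "ok"
  expect_true(any(ok))
  expect_lt(max(abs(st$residual[ok])), 1e-3 * max(st$target))
})

test_that("quasi-steady inversion recovers a static pore from its own spike", {
  geom <- std_geometry()
  q <- 0.5e-12
  c0 <- initial_concentration(q, geom$vesicle_radius)
  traj <- pore_trajectory(c(0, 5e-3), c(10e-9, 10e-9))
  qs <- quasi_steady_current(geom, transport_params(), c0, traj, 5e-3)
  inv <- quasi_steady_reconstruct(as_spike(qs$time, qs$current),
    geom$vesicle_radius,
    q = q
  )
  ok <- inv$flag == "ok"
  expect_true(sum(ok) > 40)
  expect_lt(max(abs(inv$radius[ok] - 10e-9) / 10e-9), 0.01)
  ## a zero sample maps to radius zero with a flag
  zeroed <- as_spike(qs$time, c(0, qs$current[-1]))
  inv0 <- quasi_steady_reconstruct(zeroed, geom$vesicle_radius, q = q)
  expect_identical(inv0$flag[1], "nonpositive")
  expect_equal(inv0$radius[1], 0)
})

test_that("sequential fit and closed-form oracle agree on a shared spike", {
  geom <- std_geometry()
  q <- 0.5e-12
  lt <- logistic_trajectory(20e-9, 0.8e-3, 0.25e-3, 3e-3)
  syn <- synth_spike(lt, q, geom, noise_sd_frac = 0, backend = "quasi-steady")
  fesa <- reconstruct_pore_trajectory(syn$spike, geom$vesicle_radius, q = q)
  oracle <- quasi_steady_reconstruct(syn$spike, geom$vesicle_radius, q = q)
  t95 <- 0.8e-3 + 0.25e-3 * log(19)
  phase <- fesa$trajectory$time > 0 & fesa$trajectory$time <= t95
  nf <- fesa$trajectory$radius / max(fesa$trajectory$radius)
  no <- oracle$radius / max(oracle$radius)
  expect_lt(sqrt(mean((nf[phase] - no[phase])^2)), 0.10)
})

test_that("currents demanding radii beyond the bound are clipped and flagged", {
  geom <- std_geometry()
  q <- 0.5e-12
  c0 <- initial_concentration(q, geom$vesicle_radius)
  traj <- pore_trajectory(c(0, 2e-3), c(10e-9, 10e-9))
  qs <- quasi_steady_current(geom, transport_params(), c0, traj, 2e-3)
  hot <- as_spike(qs$time, qs$current * 100)
  inv <- quasi_steady_reconstruct(hot, geom$vesicle_radius, q = q)
  expect_true(any(inv$flag == "clipped"))
  expect_true(all(inv$radius <= 0.8 * geom$vesicle_radius + 1e-15))
})

test_that("reconstruction rejects malformed spikes", {
  expect_error(
    reconstruct_pore_trajectory(as_spike(c(0, 1e-4), c(0, 1e-12)), 150e-9, q = 1e-13),
    class = "poretrace_validation_error"
  )
  bad <- tibble::tibble(time = c(0, 1e-4, 3e-4, 4e-4), current = rep(1e-12, 4))
  expect_error(reconstruct_pore_trajectory(bad, 150e-9, q = 1e-13),
    class = "poretrace_validation_error"
  )
})
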