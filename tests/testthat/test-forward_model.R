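test_that("initial concentration follows Faraday's law over the lumen volume", {
  expect_equal(initial_concentration(0, 1.5e-7), 0)
  ## hand arithmetic: V = 1.4137e-20 m^3, moles = Q/(2F) = 5.182e-18
  expect_equal(initial_concentration(1e-12, 1.5e-7), 366.56, tolerance = 1e-3)
  c1 <- initial_concentration(1e-12, 1e-7)
  c2 <- initial_concentration(1e-12, 2e-7)
  expect_equal(c1 / c2, 8)
  expect_error(initial_concentration(1e-12, -1e-7), class = "poretrace_domain_error")
})

test_that("released charge integrates by the trapezoid rule", {
  expect_equal(released_charge(tibble::tibble(time = c(0, 1e-3), current = c(0, 0))), 0)
  tr <- tibble::tibble(time = seq(0, 1e-3, 1e-4), current = rep(1e-12, 11))
  expect_equal(released_charge(tr), 1e-15)
  expect_error(released_charge(tibble::tibble(time = numeric(0), current = numeric(0))),
    class = "poretrace_validation_error"
  )
})

test_that("a pore at the seed radius 1e-10 m releases essentially nothing", {
  geom <- std_geometry()
  trp <- transport_params()
  c0 <- initial_concentration(1e-12, geom$vesicle_radius)
  cfg <- coarse_config()
  tiny <- simulate_current(
    geom, trp, c0,
    pore_trajectory(c(0, 1e-3), c(1e-10, 1e-10)), 1e-3, cfg
  )
  open <- simulate_current(
    geom, trp, c0,
    pore_trajectory(c(0, 1e-3), c(10e-9, 10e-9)), 1e-3, cfg
  )
  expect_lt(max(tiny$current), 2e-3 * max(open$current))
  expect_lt(max(tiny$current), 5e-13)
  ## no content, no current
  zero <- simulate_current(
    geom, trp, 0,
    pore_trajectory(c(0, 5e-4), c(10e-9, 10e-9)), 5e-4, cfg
  )
  expect_equal(max(abs(zero$current)), 0)
})

test_that("simulated charge is conserved and currents stay non-negative", {
  geom <- std_geometry()
  trp <- transport_params()
  q_in <- 1e-12
  c0 <- initial_concentration(q_in, geom$vesicle_radius)
  traj <- pore_trajectory(c(0, 60e-3), c(10e-9, 10e-9))
  trc <- simulate_current(geom, trp, c0, traj, 55e-3, coarse_config())
  expect_lt(trc$current[nrow(trc)], 1e-3 * max(trc$current))
  expect_true(all(trc$current >= 0))
  expect_equal(released_charge(trc), q_in, tolerance = 0.01)
})

test_that("current increases with static pore radius", {
  geom <- std_geometry()
  trp <- transport_params()
  c0 <- initial_concentration(1e-12, geom$vesicle_radius)
  cfg <- coarse_config()
  radii <- c(2e-9, 5e-9, 10e-9, 20e-9, 40e-9)
  at_03ms <- vapply(radii, function(r) {
    tr <- simulate_current(
      geom, trp, c0,
      pore_trajectory(c(0, 3e-4), c(r, r)), 3e-4, cfg
    )
    tr$current[nrow(tr)]
  }, numeric(1))
  expect_true(all(diff(at_03ms) > 0))
})

test_that("full PDE agrees with the quasi-steady oracle for small static pores", {
  geom <- std_geometry()
  trp <- transport_params()
  c0 <- initial_concentration(1e-12, geom$vesicle_radius)
  traj <- pore_trajectory(c(0, 3e-3), c(10e-9, 10e-9)) # r = 0.067 R_ves
  pde <- simulate_current(geom, trp, c0, traj, 2e-3, coarse_config())
  qs <- quasi_steady_current(geom, trp, c0, traj, 2e-3)
  after <- pde$time > 2e-4 # past the initial transient
  rel <- abs(pde$current[after] - qs$current[after]) / qs$current[after]
  expect_lt(max(rel), 0.15)
})

test_that("halving mesh size and time step changes the current by < 1% RMS", {
  geom <- std_geometry()
  trp <- transport_params()
  c0 <- initial_concentration(0.5e-12, geom$vesicle_radius)
  traj <- pore_trajectory(c(0, 4e-3), c(10e-9, 10e-9))
  base <- simulate_current(geom, trp, c0, traj, 4e-3)
  fine <- simulate_current(
    geom, trp, c0, traj, 4e-3,
    sim_config(dt = 5e-6, cell_near_pore = 0.125e-9, growth_fine = 1.03)
  )
  rms <- sqrt(mean((base$current - fine$current)^2)) / max(fine$current)
  expect_lt(rms, 0.01)
})

test_that("quasi-steady model matches hand arithmetic and its closed form", {
  geom <- std_geometry()
  trp <- transport_params()
  ## R_diff(10 nm) ~ 4.85e17 s/m^3; I = nF C / R_diff ~ 1.46e-10 A
  rd <- diffusive_resistance(10e-9, geom, trp)
  expect_equal(rd, 4.8486e17, tolerance = 1e-3)
  expect_equal(2 * 96485 * 366.6 / rd, 1.459e-10, tolerance = 1e-2)
  expect_equal(diffusive_resistance(0, geom, trp), Inf)

  ## static pore: exponential decay with tau = V R_diff
  c0 <- 366.6
  traj <- pore_trajectory(c(0, 5e-3), c(10e-9, 10e-9))
  qs <- quasi_steady_current(geom, trp, c0, traj, 5e-3)
  vol <- (4 / 3) * pi * geom$vesicle_radius^3
  tau <- vol * rd
  expected <- qs$current[1] * exp(-qs$time / tau)
  expect_equal(qs$current, expected, tolerance = 1e-3)
})

test_that("gap sweep returns one trace per gap and matches the default", {
  geom <- std_geometry()
  trp <- transport_params()
  c0 <- initial_concentration(0.5e-12, geom$vesicle_radius)
  lt <- logistic_trajectory(15e-9, 0.4e-3, 0.15e-3, 1e-3)
  cfg <- coarse_config()
  gs <- gap_sensitivity(geom, trp, c0, lt, 1e-3, gaps = 20e-9, config = cfg)
  ref <- simulate_current(geom, trp, c0, lt, 1e-3, cfg)
  expect_equal(gs$current, ref$current)
  empty <- gap_sensitivity(geom, trp, c0, lt, 1e-3, gaps = numeric(0), config = cfg)
  expect_equal(nrow(empty), 0)
})
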