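#' Simulate the amperometric current for a prescribed pore trajectory
#'
#' Solves Fick's second law on the axisymmetric release geometry: the lumen
#' starts at uniform concentration `c0` (zero in the pore and bath), the
#' electrode plane is an absorbing (C = 0) disk representing
#' diffusion-limited oxidation, every other boundary and the vesicle
#' membrane are no-flux, diffusion is `d_in` inside the lumen and `d_out` in
#' the pore/gap/bath, and the pore radius follows `traj` (piecewise linear)
#' while the field is advanced by backward Euler.  The returned current is
#' Faraday's-law conversion of the surface-integrated normal flux across the
#' pore cross-section.
#'
#' The discrete lumen volume (cells whose centres fall inside the sphere)
#' deviates from \eqn{\tfrac{4}{3}\pi R_{ves}^3} by the staircase error, so
#' the initial field is scaled to hold exactly `c0 * (4/3) pi R_ves^3` moles:
#' the simulated spike then integrates back to the charge that defined `c0`.
#'
#' @param geometry A [vesicle_geometry()].
#' @param transport A [transport_params()].
#' @param c0 Initial lumen concentration (mol/m^3), from
#'   [initial_concentration()].
#' @param traj A [pore_trajectory()] spanning `[0, t_end]`; radii must stay
#'   below `0.8 * vesicle_radius`.
#' @param t_end End time of the simulation (s).
#' @param config A [sim_config()].
#' @return A `current_trace` tibble with columns `time` (s) and `current`
#'   (A), sampled every `config$dt_output`.
#' @examples
#' \donttest{
#' geom <- vesicle_geometry(150e-9)
#' traj <- logistic_trajectory(15e-9, 1e-3, 0.3e-3, 4e-3)
#' tr <- simulate_current(geom, transport_params(), 366, traj, 4e-3)
#' released_charge(tr)
#' }
#' @export
simulate_current <- function(geometry, transport, c0, traj, t_end,
                             config = sim_config()) {
  validate_traj_for_geometry(traj, geometry, t_end)
  if (c0 < 0) abort("c0 must be >= 0", class = "poretrace_validation_error")
  ctx <- build_pde_context(geometry, transport, config)
  moles0 <- c0 * (4 / 3) * pi * geometry$vesicle_radius^3
  C <- numeric(ctx$n)
  C[ctx$lumen_ids] <- if (moles0 > 0) moles0 / ctx$V_lumen else 0
  times <- seq(0, t_end, by = config$dt_output)
  currents <- numeric(length(times))
  r_prev <- pore_radius_at(traj, 0)
  for (k in seq_along(times)[-1]) {
    r_next <- pore_radius_at(traj, times[k])
    st <- advance_pde(ctx, C, r_prev, r_next, times[k] - times[k - 1], moles0)
    C <- st$C
    currents[k] <- st$I
    r_prev <- r_next
  }
  new_current_trace(times, currents, geometry, transport)
}

new_current_trace <- function(time, current, geometry = NULL, transport = NULL) {
  out <- new_tibble(list(time = as.numeric(time), current = as.numeric(current)),
    class = "current_trace"
  )
  attr(out, "geometry") <- geometry
  attr(out, "transport") <- transport
  out
}

validate_traj_for_geometry <- function(traj, geometry, t_end) {
  if (max(traj$radius) > 0.8 * geometry$vesicle_radius + 1e-18) {
    abort("trajectory radius exceeds 0.8 * vesicle_radius",
      class = "poretrace_validation_error"
    )
  }
  if (traj$time[nrow(traj)] < t_end - 1e-12) {
    abort("trajectory must span [0, t_end]", class = "poretrace_validation_error")
  }
  invisible(traj)
}

#' Charge released over a current trace
#'
#' Trapezoidal integration of I(t); by Faraday's law this is the amount of
#' transmitter oxidised (times nF).
#'
#' @param trace A `current_trace` (or any tibble with `time` and `current`).
#' @return Charge (C).
#' @export
released_charge <- function(trace) {
  if (nrow(trace) == 0) {
    abort("trace is empty", class = "poretrace_validation_error")
  }
  trapz(trace$time, trace$current)
}

trapz <- function(x, y) {
  if (length(x) < 2) {
    return(0)
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Sensitivity of the simulated spike to the vesicle-electrode gap
#'
#' Re-runs [simulate_current()] with the pore-bottom-to-electrode distance
#' swept over `gaps`, everything else fixed.  Over 2--20 nm the traces
#' nearly overlap: the gap film is thin and the electrode absorbing, so the
#' pore, not the gap, limits transport.
#'
#' @inheritParams simulate_current
#' @param gaps Numeric vector of gap distances (m).
#' @return A tibble with columns `gap`, `time`, `current` (one trace per
#'   gap, row-bound).
#' @export
gap_sensitivity <- function(geometry, transport, c0, traj, t_end,
                            gaps = c(2e-9, 20e-9), config = sim_config()) {
  purrr::map_dfr(gaps, function(g) {
    geo <- vesicle_geometry(
      vesicle_radius = geometry$vesicle_radius,
      pore_length = geometry$pore_length, gap = g,
      electrode_radius = geometry$electrode_radius,
      domain_radius = geometry$domain_radius,
      domain_height = geometry$domain_height
    )
    tr <- simulate_current(geo, transport, c0, traj, t_end, config)
    tibble(gap = g, time = tr$time, current = tr$current)
  })
}
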