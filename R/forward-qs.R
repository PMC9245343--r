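#' Quasi-steady diffusive resistance of the pore path
#'
#' Lumped series resistance (s/m^3) between the well-mixed lumen and the
#' absorbing electrode for a pore of radius `r`: converging access
#' resistance inside the lumen, channel resistance of the cylindrical pore,
#' and spreading access resistance outside,
#' \deqn{R_{diff}(r) = \frac{1}{4 D_{in} r} + \frac{L}{D_{out}\pi r^2} +
#'   \frac{1}{4 D_{out} r}.}
#' `r = 0` gives `Inf` (no flow).
#'
#' @param r Pore radius (m), vectorised.
#' @param geometry A [vesicle_geometry()] (only `pore_length` is used).
#' @param transport A [transport_params()].
#' @return Resistance (s/m^3).
#' @export
diffusive_resistance <- function(r, geometry, transport = transport_params()) {
  ifelse(r > 0,
    1 / (4 * transport$d_in * r) +
      geometry$pore_length / (transport$d_out * pi * r^2) +
      1 / (4 * transport$d_out * r),
    Inf
  )
}

#' Quasi-steady reduced-order current model
#'
#' Independent lumped oracle for [simulate_current()]: the lumen is treated
#' as well mixed with molar content N(t), draining through the quasi-steady
#' resistance of [diffusive_resistance()],
#' \deqn{N'(t) = -\frac{N(t)/V_{ves}}{R_{diff}(r(t))}, \qquad
#'   I(t) = n F |N'(t)|.}
#' Integration uses midpoint-exponential sub-steps (exact for a static
#' pore, where the decay is a single exponential with
#' \eqn{\tau = V_{ves} R_{diff}}).
#'
#' @inheritParams simulate_current
#' @param dt_output Output sampling interval (s).
#' @param substeps Integration sub-steps per output interval.
#' @return A `current_trace` tibble (`time`, `current`).
#' @examples
#' geom <- vesicle_geometry(150e-9)
#' traj <- pore_trajectory(c(0, 5e-3), c(10e-9, 10e-9))
#' qs <- quasi_steady_current(geom, transport_params(), 366.6, traj, 5e-3)
#' @export
quasi_steady_current <- function(geometry, transport, c0, traj, t_end,
                                 dt_output = 1e-4, substeps = 25L) {
  validate_traj_for_geometry(traj, geometry, t_end)
  vol <- (4 / 3) * pi * geometry$vesicle_radius^3
  nF <- transport$n_electrons * transport$faraday
  N <- c0 * vol
  times <- seq(0, t_end, by = dt_output)
  currents <- numeric(length(times))
  currents[1] <- qs_current_now(N, vol, pore_radius_at(traj, 0), geometry, transport, nF)
  for (k in seq_along(times)[-1]) {
    st <- advance_qs(
      N, times[k - 1], pore_radius_at(traj, times[k - 1]),
      pore_radius_at(traj, times[k]), times[k] - times[k - 1],
      vol, geometry, transport, substeps
    )
    N <- st$N
    currents[k] <- st$I
  }
  new_current_trace(times, currents, geometry, transport)
}

qs_current_now <- function(N, vol, r, geometry, transport, nF) {
  Rd <- diffusive_resistance(r, geometry, transport)
  if (!is.finite(Rd)) {
    return(0)
  }
  nF * (N / vol) / Rd
}

## advance the lumped content over `span` with radius linear r_from -> r_to
advance_qs <- function(N, t0, r_from, r_to, span, vol, geometry, transport,
                       substeps = 25L) {
  nF <- transport$n_electrons * transport$faraday
  h <- span / substeps
  for (k in seq_len(substeps)) {
    r_mid <- r_from + (r_to - r_from) * (k - 0.5) / substeps
    Rd <- diffusive_resistance(r_mid, geometry, transport)
    rate <- if (is.finite(Rd)) 1 / (vol * Rd) else 0
    N <- N * exp(-rate * h)
  }
  list(N = N, I = qs_current_now(N, vol, r_to, geometry, transport, nF))
}
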