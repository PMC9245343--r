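#' Geometric description of a vesicle adsorbed on a microdisk electrode
#'
#' Fixes the axisymmetric release geometry used throughout the package: a
#' spherical vesicle of radius `vesicle_radius` whose membrane is pierced at
#' its bottom pole by a cylindrical pore of length `pore_length`, separated
#' from the absorbing electrode plane by an aqueous `gap` (the space held
#' open by membrane proteins pushing the membrane off the electrode).  All
#' lengths are in metres (SI units are used everywhere inside the package;
#' only plotting and CLI summaries convert to nm/ms/pA).
#'
#' @param vesicle_radius Vesicle radius \eqn{R_{ves}} (m), typically from a
#'   resistive-pulse measurement.
#' @param pore_length Pore channel length (m); default `5e-9`, close to the
#'   membrane thickness.
#' @param gap Distance from the pore bottom to the electrode surface (m);
#'   default `20e-9`.  Simulated currents are insensitive to this value over
#'   2--20 nm (see [gap_sensitivity()]).
#' @param electrode_radius Radius of the absorbing microdisk (m); default
#'   `2.5e-6` (5 um diameter), large enough to oxidise everything released.
#' @param domain_radius,domain_height Outer extents of the simulation
#'   cylinder (m).  Defaults: `electrode_radius` and `2e-6`.  The domain must
#'   enclose the vesicle with a margin of at least `2 * vesicle_radius` so
#'   the no-flux outer wall is irrelevant over a spike.
#'
#' @return An object of class `vesicle_geometry` (a named list).
#' @examples
#' geom <- vesicle_geometry(150e-9)
#' geom$pore_length
#' @export
vesicle_geometry <- function(vesicle_radius,
                             pore_length = 5e-9,
                             gap = 20e-9,
                             electrode_radius = 2.5e-6,
                             domain_radius = electrode_radius,
                             domain_height = 2e-6) {
  lens <- c(
    vesicle_radius = vesicle_radius, pore_length = pore_length, gap = gap,
    electrode_radius = electrode_radius, domain_radius = domain_radius,
    domain_height = domain_height
  )
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    abort("all geometry lengths must be finite and > 0", class = "poretrace_domain_error")
  }
  if (electrode_radius < 0.8 * vesicle_radius) {
    abort("electrode must fully cover the projected pore footprint (0.8 * R_ves)",
      class = "poretrace_domain_error"
    )
  }
  sphere_top <- gap + pore_length + 2 * vesicle_radius
  if (domain_height < sphere_top + 2 * vesicle_radius ||
    domain_radius < 3 * vesicle_radius) {
    abort("outer domain must enclose the vesicle with margin >= 2 * R_ves",
      class = "poretrace_domain_error"
    )
  }
  structure(as.list(lens), class = "vesicle_geometry")
}

#' @export
print.vesicle_geometry <- function(x, ...) {
  cat("<vesicle_geometry>\n")
  cat(sprintf("  R_ves      %8.1f nm\n", x$vesicle_radius * 1e9))
  cat(sprintf("  pore length%8.1f nm\n", x$pore_length * 1e9))
  cat(sprintf("  gap        %8.1f nm\n", x$gap * 1e9))
  cat(sprintf("  electrode  %8.2f um radius\n", x$electrode_radius * 1e6))
  cat(sprintf(
    "  domain     %.2f um x %.2f um\n",
    x$domain_radius * 1e6, x$domain_height * 1e6
  ))
  invisible(x)
}

#' Volume fraction lost to a spherical cap
#'
#' Fraction of a sphere's volume contained in the cap cut off at a chord
#' (pore) radius equal to `ratio` times the sphere radius: with
#' \eqn{\sin\theta = ratio}, cap height \eqn{h = R(1 - \cos\theta)} and
#' \eqn{V_{cap} = (\pi/3) h^2 (3R - h)}.  Used to justify keeping the vesicle
#' sphere fixed while the pore opens: for pore/vesicle radius ratios below
#' 1/3 the lost volume is under 0.8% of the sphere.
#'
#' @param ratio Pore radius divided by vesicle radius, in `[0, 1]`.
#' @return Dimensionless volume fraction in `[0, 0.5]`.
#' @examples
#' spherical_cap_fraction(0.3) # ~1.57e-3
#' @export
spherical_cap_fraction <- function(ratio) {
  check_ratio(ratio)
  cos_theta <- sqrt(1 - ratio^2)
  h <- 1 - cos_theta # in units of R
  (pi / 3) * h^2 * (3 - h) / ((4 / 3) * pi)
}

#' Angular aperture of the pore rim
#'
#' Half-angle (degrees) subtended at the vesicle centre by the pore rim,
#' `asin(ratio)`.  A ratio of 1/3 corresponds to ~19.47 degrees.
#'
#' @inheritParams spherical_cap_fraction
#' @return Angle in degrees, in `[0, 90]`.
#' @examples
#' angular_aperture_deg(1 / 3)
#' @export
angular_aperture_deg <- function(ratio) {
  check_ratio(ratio)
  asin(ratio) * 180 / pi
}

check_ratio <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio < 0) || any(ratio > 1)) {
    abort("`ratio` must lie in [0, 1]", class = "poretrace_domain_error")
  }
  invisible(ratio)
}
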