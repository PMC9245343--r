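#' Transport parameters for catecholamine diffusion and oxidation
#'
#' Diffusion is slower inside the crowded vesicle lumen than in the pore and
#' bath; both coefficients are taken from the amperometry literature.
#' Oxidation at the electrode transfers `n_electrons` per molecule (2 for
#' catecholamines), converting molar flux to current via Faraday's law.
#'
#' @param d_in Diffusion coefficient inside the vesicle lumen (m^2/s),
#'   default `6.0e-11`.
#' @param d_out Diffusion coefficient within the pore and outside the
#'   vesicle (m^2/s), default `6.0e-10`.
#' @param n_electrons Electrons transferred per molecule oxidised; default 2.
#' @param faraday Faraday constant (C/mol).
#' @return A `transport_params` object (named list).
#' @examples
#' transport_params()
#' @export
transport_params <- function(d_in = 6.0e-11, d_out = 6.0e-10,
                             n_electrons = 2L, faraday = 96485) {
  if (d_in <= 0 || d_out <= 0) {
    abort("diffusion coefficients must be > 0", class = "poretrace_domain_error")
  }
  if (n_electrons < 1) {
    abort("n_electrons must be >= 1", class = "poretrace_domain_error")
  }
  structure(
    list(
      d_in = d_in, d_out = d_out,
      n_electrons = as.integer(n_electrons), faraday = faraday
    ),
    class = "transport_params"
  )
}

#' Numerical configuration of the forward solver
#'
#' Controls the finite-volume discretisation and time stepping of
#' [simulate_current()].  The defaults resolve pores down to ~1 nm radius
#' directly; smaller radii use a smooth sub-mesh conductance blend.
#'
#' @param dt Internal backward-Euler time step (s).  Must be at most
#'   `dt_output / 10`; default `1e-5`.
#' @param dt_output Output sampling interval (s); default `1e-4`, the
#'   sampling interval of VIEC current data.
#' @param cell_near_pore Target cell size next to the pore axis (m);
#'   default `0.25e-9`.
#' @param growth_fine,growth_coarse Geometric mesh-grading ratios near the
#'   pore and in the far field.
#' @param gap_cells Number of cells across the vesicle-electrode gap.
#' @return A `sim_config` object (named list).
#' @export
sim_config <- function(dt = 1e-5, dt_output = 1e-4,
                       cell_near_pore = 0.25e-9,
                       growth_fine = 1.06, growth_coarse = 1.3,
                       gap_cells = 5L) {
  if (dt <= 0 || dt_output <= 0) {
    abort("time steps must be > 0", class = "poretrace_validation_error")
  }
  if (dt > dt_output / 10 + 1e-15) {
    abort("internal time step must be <= dt_output / 10",
      class = "poretrace_validation_error"
    )
  }
  if (cell_near_pore <= 0 || growth_fine <= 1 || growth_coarse <= 1) {
    abort("mesh parameters out of range", class = "poretrace_validation_error")
  }
  structure(
    list(
      dt = dt, dt_output = dt_output, cell_near_pore = cell_near_pore,
      growth_fine = growth_fine, growth_coarse = growth_coarse,
      gap_cells = as.integer(gap_cells)
    ),
    class = "sim_config"
  )
}

#' Initial lumen concentration from the spike charge
#'
#' The catecholamine content of one vesicle is obtained from the total
#' charge `Q` of its current spike via Faraday's law and converted to a
#' concentration over the spherical lumen volume:
#' \deqn{C_0 = \frac{Q}{n F \tfrac{4}{3}\pi R_{ves}^3}.}
#'
#' @param q Spike charge (C), >= 0.
#' @param vesicle_radius Vesicle radius (m), > 0.
#' @param transport A [transport_params()] object.
#' @return Concentration (mol/m^3).
#' @examples
#' initial_concentration(1e-12, 150e-9) # ~366.6 mol/m^3
#' @export
initial_concentration <- function(q, vesicle_radius, transport = transport_params()) {
  if (vesicle_radius <= 0) {
    abort("vesicle_radius must be > 0", class = "poretrace_domain_error")
  }
  if (q < 0) {
    abort("charge must be >= 0", class = "poretrace_domain_error")
  }
  vol <- (4 / 3) * pi * vesicle_radius^3
  q / (transport$n_electrons * transport$faraday * vol)
}
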