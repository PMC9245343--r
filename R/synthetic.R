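#' Logistic pore-opening trajectory
#'
#' Canonical synthetic trajectory family: reconstructed pores rise
#' sigmoidally to a plateau, which a logistic captures with three
#' parameters,
#' \deqn{r(t) = \frac{R_{max}}{1 + e^{-(t - t_{50})/s}}.}
#' Its 5--95% expansion time is exactly `2 * steepness * log(19)`.
#'
#' @param r_max Plateau pore radius (m), > 0.
#' @param t_mid Midpoint time \eqn{t_{50}} (s).
#' @param steepness Logistic time scale `s` (s), > 0.
#' @param t_end Final knot time (s).
#' @param dt Knot spacing (s); default `1e-4`, the VIEC sampling interval.
#' @return A [pore_trajectory()].
#' @examples
#' traj <- logistic_trajectory(15e-9, 1e-3, 0.3e-3, 4e-3)
#' pore_features(traj) # t_expa = 2 * 0.3e-3 * log(19)
#' @export
logistic_trajectory <- function(r_max, t_mid, steepness, t_end, dt = 1e-4) {
  if (r_max <= 0 || steepness <= 0) {
    abort("r_max and steepness must be > 0", class = "poretrace_validation_error")
  }
  t <- seq(0, t_end, by = dt)
  if (t[length(t)] < t_end) t <- c(t, t_end)
  pore_trajectory(t, r_max / (1 + exp(-(t - t_mid) / steepness)))
}

#' Synthesise a spike from a known pore trajectory
#'
#' Forward-simulates the trajectory and adds Gaussian noise, returning both
#' the noisy spike and the ground truth -- the closed-loop test harness for
#' the reconstruction algorithm, standing in for the undeposited raw
#' recordings.
#'
#' @param trajectory A [pore_trajectory()] (ground truth).
#' @param q Spike charge (C) carried by the vesicle content.
#' @param geometry A [vesicle_geometry()].
#' @param transport A [transport_params()].
#' @param t_end Simulation end time (s); defaults to the last knot.
#' @param noise_sd_frac Gaussian noise SD as a fraction of the peak
#'   current; default 0.02.
#' @param seed Integer seed; mandatory when `noise_sd_frac > 0`.
#' @param backend `"full-pde"` or `"quasi-steady"` forward model.
#' @param config [sim_config()] for the PDE backend.
#' @return List with `spike` (an [as_spike()] with `baseline_sd` set to the
#'   injected noise SD), `trace` (the noiseless forward trace), and
#'   `truth` (the input trajectory).
#' @export
synth_spike <- function(trajectory, q, geometry, transport = transport_params(),
                        t_end = NULL, noise_sd_frac = 0.02, seed = NULL,
                        backend = c("quasi-steady", "full-pde"),
                        config = sim_config()) {
  backend <- match.arg(backend)
  if (is.null(t_end)) t_end <- trajectory$time[nrow(trajectory)]
  c0 <- initial_concentration(q, geometry$vesicle_radius, transport)
  trace <- if (backend == "full-pde") {
    simulate_current(geometry, transport, c0, trajectory, t_end, config)
  } else {
    quasi_steady_current(geometry, transport, c0, trajectory, t_end,
      dt_output = config$dt_output
    )
  }
  noise_sd <- noise_sd_frac * max(trace$current)
  current <- trace$current
  if (noise_sd > 0) {
    if (is.null(seed)) {
      abort("a seed is required for noisy synthesis",
        class = "poretrace_validation_error"
      )
    }
    current <- current + with_local_seed(seed, rnorm(length(current), 0, noise_sd))
  }
  list(
    spike = as_spike(trace$time, current, baseline_sd = noise_sd),
    trace = trace, truth = trajectory
  )
}

## run code with a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Statistical description of a synthetic vesicle population
#'
#' Defaults emulate the measured spread of chromaffin-vesicle data: vesicle
#' radii log-normal around 150 nm; spike charges log-normal around 0.5 pC;
#' maximum pore radii following the empirical log-log scaling law (slope
#' 3.43, intercept 15.26 in log10 metres) with log-normal scatter, spanning
#' pore diameters of roughly 6--280 nm across the size range; expansion
#' times log-normal with median 2.08 ms (vesicles, wide spread) or 0.18 ms
#' (liposomes, narrow spread), matching the reported medians and quartiles.
#'
#' @param r_ves_median Median vesicle radius (m).
#' @param r_ves_sdlog Log-SD of the vesicle radius.
#' @param q_median,q_sdlog Median (C) and log-SD of the spike charge.
#' @param scaling_slope,scaling_intercept Scaling law for `r_p_max`
#'   (log10 m as a function of log10 `r_ves`).
#' @param scaling_sdlog10 SD of the log10 scatter around the scaling law.
#' @param t_expa_median_vesicle,t_expa_sdlog_vesicle Vesicle-group
#'   expansion-time distribution (s, log scale).
#' @param t_expa_median_liposome,t_expa_sdlog_liposome Liposome-group
#'   expansion-time distribution.
#' @param noise_sd_frac Spike noise fraction carried along for spike
#'   synthesis.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(r_ves_median = 150e-9, r_ves_sdlog = 0.35,
                       q_median = 0.5e-12, q_sdlog = 0.5,
                       scaling_slope = 3.43, scaling_intercept = 15.26,
                       scaling_sdlog10 = 0.12,
                       t_expa_median_vesicle = 2.08e-3,
                       t_expa_sdlog_vesicle = 0.98,
                       t_expa_median_liposome = 0.18e-3,
                       t_expa_sdlog_liposome = 0.24,
                       noise_sd_frac = 0.02) {
  spec <- as.list(environment())
  stopifnot(all(vapply(spec, function(v) is.numeric(v) && is.finite(v), logical(1))))
  scales <- spec[setdiff(names(spec), c("scaling_slope", "scaling_intercept"))]
  stopifnot(all(vapply(scales, function(v) v > 0, logical(1))))
  structure(spec, class = "synth_spec")
}

#' Draw a synthetic vesicle population
#'
#' Draws `n` vesicles (or liposomes) from a [synth_spec()]: sizes and
#' charges log-normal, maximum pore radii from the configured scaling law
#' with log-normal scatter (rejection-resampled so every `r_p_max` stays
#' below its `r_ves`), and 5--95% expansion/rise times from the
#' group-specific log-normal distributions (`t_rise` tracks `t_expa` with
#' 10% jitter, mirroring their near-equivalence).
#'
#' @param n Number of records, >= 1.
#' @param spec A [synth_spec()].
#' @param group `"vesicle"` or `"liposome"` (sets the expansion-time
#'   distribution and the group label).
#' @param seed Integer seed (mandatory).
#' @return Tibble with columns `r_ves`, `r_p_max`, `t_expa`, `t_rise`
#'   (SI units) and `group`.
#' @examples
#' pop <- synth_population(50, synth_spec(), seed = 1)
#' loglog_scaling_fit(pop)
#' @export
synth_population <- function(n, spec = synth_spec(),
                             group = c("vesicle", "liposome"), seed) {
  group <- match.arg(group)
  if (n < 1) abort("n must be >= 1", class = "poretrace_validation_error")
  if (missing(seed) || is.null(seed)) {
    abort("a seed is required", class = "poretrace_validation_error")
  }
  with_local_seed(seed, {
    r_ves <- rlnorm(n, log(spec$r_ves_median), spec$r_ves_sdlog)
    draw_rp <- function(rv) {
      10^(spec$scaling_slope * log10(rv) + spec$scaling_intercept +
        rnorm(length(rv), 0, spec$scaling_sdlog10))
    }
    r_p_max <- draw_rp(r_ves)
    ## rejection-resample any draw implying a pore larger than its vesicle
    for (tries in 1:100) {
      bad <- r_p_max >= r_ves
      if (!any(bad)) break
      r_p_max[bad] <- draw_rp(r_ves[bad])
    }
    r_p_max <- pmin(r_p_max, 0.99 * r_ves)
    med <- if (group == "vesicle") spec$t_expa_median_vesicle else spec$t_expa_median_liposome
    sdl <- if (group == "vesicle") spec$t_expa_sdlog_vesicle else spec$t_expa_sdlog_liposome
    t_expa <- rlnorm(n, log(med), sdl)
    t_rise <- t_expa * rlnorm(n, 0, 0.1)
    tibble(
      r_ves = r_ves, r_p_max = r_p_max, t_expa = t_expa,
      t_rise = t_rise, group = group
    )
  })
}
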