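#' Configuration of the sequential pore-radius reconstruction
#'
#' Defaults follow the published protocol: search zone from `1e-11` m to
#' `0.8 * R_ves`, argument tolerance `1e-11` m, initial radius `1e-10` m
#' (small enough that the initial outflow is effectively zero), one fitted
#' knot per 0.1 ms current sample.
#'
#' @param lower_bound Lower search bound for the pore radius (m).
#' @param upper_factor Upper bound as a fraction of the vesicle radius.
#' @param tolerance Argument tolerance of the one-dimensional search (m).
#' @param initial_radius Pore radius at t = 0 (m).
#' @param backend Forward model used inside the fit: `"quasi-steady"`
#'   (lumped, fast) or `"full-pde"` (finite-volume diffusion solve).
#' @param depletion_cutoff Released fraction of the charge beyond which
#'   fitted radii are flagged `"depleted"`: past this point the current no
#'   longer constrains the pore.
#' @param sim A [sim_config()] for the `"full-pde"` backend.
#' @param qs_substeps Integration sub-steps per sample for the
#'   `"quasi-steady"` backend.
#' @param monotone If `TRUE`, apply a post-hoc monotone (running-maximum)
#'   projection to the reconstructed radii.  Off by default: no
#'   monotonicity constraint is imposed during fitting.
#' @return A `recon_config` object (named list).
#' @export
recon_config <- function(lower_bound = 1e-11, upper_factor = 0.8,
                         tolerance = 1e-11, initial_radius = 1e-10,
                         backend = c("quasi-steady", "full-pde"),
                         depletion_cutoff = 0.95,
                         sim = sim_config(), qs_substeps = 25L,
                         monotone = FALSE) {
  backend <- match.arg(backend)
  if (lower_bound <= 0 || upper_factor <= 0 || upper_factor > 1) {
    abort("invalid search bounds", class = "poretrace_validation_error")
  }
  if (tolerance <= 0) {
    abort("tolerance must be > 0", class = "poretrace_validation_error")
  }
  structure(
    list(
      lower_bound = lower_bound, upper_factor = upper_factor,
      tolerance = tolerance, initial_radius = initial_radius,
      backend = backend, depletion_cutoff = depletion_cutoff,
      sim = sim, qs_substeps = as.integer(qs_substeps), monotone = monotone
    ),
    class = "recon_config"
  )
}

#' Initialise a forward-model state for sequential fitting
#'
#' Builds the forward solver (full PDE or quasi-steady) at t = 0 with the
#' lumen loaded from the spike charge `q`.  The returned state is advanced
#' step by step by [fit_step()]; it is an immutable snapshot, so candidate
#' evaluations inside the fit never corrupt the checkpoint.
#'
#' @inheritParams simulate_current
#' @param q Spike charge (C), > 0.
#' @param config A [recon_config()].
#' @return A `fesa_state` object.
#' @export
fesa_init <- function(geometry, transport, q, config = recon_config()) {
  if (q <= 0) abort("q must be > 0", class = "poretrace_validation_error")
  c0 <- initial_concentration(q, geometry$vesicle_radius, transport)
  vol <- (4 / 3) * pi * geometry$vesicle_radius^3
  moles0 <- c0 * vol
  st <- list(
    backend = config$backend, geometry = geometry, transport = transport,
    config = config, vol = vol, moles0 = moles0, c0 = c0,
    t = 0, r = config$initial_radius, released_frac = 0, I = 0
  )
  if (config$backend == "full-pde") {
    st$ctx <- build_pde_context(geometry, transport, config$sim)
    C <- numeric(st$ctx$n)
    C[st$ctx$lumen_ids] <- moles0 / st$ctx$V_lumen
    st$C <- C
  } else {
    st$N <- moles0
  }
  structure(st, class = "fesa_state")
}

## advance a fesa_state over `span` seconds to radius r_to (linear ramp
## from the state's current radius); pure function of the inputs
advance_fesa <- function(state, r_to, span) {
  if (state$backend == "full-pde") {
    out <- advance_pde(state$ctx, state$C, state$r, r_to, span, state$moles0)
    state$C <- out$C
    state$released_frac <- out$released_frac
  } else {
    out <- advance_qs(
      state$N, state$t, state$r, r_to, span, state$vol,
      state$geometry, state$transport, state$config$qs_substeps
    )
    state$N <- out$N
    state$released_frac <- 1 - out$N / state$moles0
  }
  state$I <- out$I
  state$t <- state$t + span
  state$r <- r_to
  state
}

#' Fit one pore-radius knot to one current sample
#'
#' One step of the sequential algorithm: starting from the forward-model
#' state at the previous sample, searches the radius `r` that minimises
#' `|I_sim(t_k; r) - target_current|`, where the forward model is advanced
#' over one sampling interval with the pore radius ramping linearly from
#' the previous knot to `r`.  The search is a one-dimensional Nelder--Mead
#' (reflection/expansion/contraction on a two-point simplex) with bound
#' clipping, terminated when the simplex width falls below `tolerance`.
#'
#' Flags: `"unidentifiable"` if `target_current` is at or below
#' `noise_floor` (previous radius is kept), `"saturated-low"` if every
#' candidate gives zero current while the target is above the floor,
#' `"clipped"` if the best fit sits at the upper bound with
#' `I_sim < target`, otherwise `"ok"`.
#'
#' @param state A `fesa_state` from [fesa_init()] (checkpoint at the
#'   previous sample).
#' @param target_current Baseline-subtracted experimental current (A) at
#'   the next sample.
#' @param bounds Length-2 search interval for the radius (m); defaults to
#'   the configured `lower_bound` and `upper_factor * R_ves`.
#' @param tolerance Argument tolerance (m).
#' @param noise_floor Currents at or below this value (A) are considered
#'   uninformative.
#' @param span Time advanced by this step (s); defaults to the output
#'   sampling interval of the state's configuration.
#' @return A list with `radius`, `flag`, `fitted_current`, `residual`,
#'   `evals`, and `state` (the checkpoint advanced with the fitted radius).
#' @export
fit_step <- function(state, target_current, bounds = NULL,
                     tolerance = NULL, noise_floor = 0, span = NULL) {
  cfg <- state$config
  if (is.null(bounds)) {
    bounds <- c(cfg$lower_bound, cfg$upper_factor * state$geometry$vesicle_radius)
  }
  if (is.null(tolerance)) tolerance <- cfg$tolerance
  if (is.null(span)) {
    span <- if (state$backend == "full-pde") cfg$sim$dt_output else 1e-4
  }
  if (target_current <= noise_floor) {
    r_hat <- min(max(state$r, bounds[1]), bounds[2])
    new_state <- advance_fesa(state, r_hat, span)
    return(list(
      radius = r_hat, flag = "unidentifiable",
      fitted_current = new_state$I, residual = new_state$I - target_current,
      evals = 1L, state = new_state
    ))
  }
  f <- function(r) abs(advance_fesa(state, r, span)$I - target_current)
  opt <- nm1d(f, x0 = state$r, lower = bounds[1], upper = bounds[2], tol = tolerance)
  r_hat <- opt$x
  new_state <- advance_fesa(state, r_hat, span)
  flag <- "ok"
  if (new_state$I <= 0 && target_current > noise_floor) {
    flag <- "saturated-low"
  } else if (bounds[2] - r_hat <= tolerance && new_state$I < target_current) {
    flag <- "clipped"
  }
  list(
    radius = r_hat, flag = flag, fitted_current = new_state$I,
    residual = new_state$I - target_current, evals = opt$evals,
    state = new_state
  )
}

## one-dimensional Nelder-Mead on [lower, upper]: two-point simplex with
## reflection (1), expansion (2), contraction (1/2), bound handling by
## clipping; a clipped reflection degenerates onto the best point, in which
## case the step falls back to bisection of the simplex
nm1d <- function(f, x0, lower, upper, tol, max_iter = 100L) {
  clamp <- function(x) min(max(x, lower), upper)
  b <- clamp(x0)
  w <- clamp(max(b * 2, b + 20 * tol))
  if (w == b) w <- clamp(b - 20 * tol)
  fb <- f(b)
  fw <- f(w)
  evals <- 2L
  if (fw < fb) {
    tmp <- b
    b <- w
    w <- tmp
    tmp <- fb
    fb <- fw
    fw <- tmp
  }
  iter <- 0L
  while (abs(b - w) > tol && iter < max_iter) {
    iter <- iter + 1L
    xr <- clamp(b + (b - w))
    if (xr == b) { # reflection clipped at a bound: bisect instead
      xc <- (b + w) / 2
      fc <- f(xc)
      evals <- evals + 1L
      if (fc < fb) {
        w <- b
        fw <- fb
        b <- xc
        fb <- fc
      } else {
        w <- xc
        fw <- fc
      }
      next
    }
    fr <- f(xr)
    evals <- evals + 1L
    if (fr < fb) {
      xe <- clamp(b + 2 * (b - w))
      if (xe != xr) {
        fe <- f(xe)
        evals <- evals + 1L
      } else {
        fe <- Inf
      }
      if (fe < fr) {
        w <- b
        fw <- fb
        b <- xe
        fb <- fe
      } else {
        w <- b
        fw <- fb
        b <- xr
        fb <- fr
      }
    } else if (fr < fw) {
      w <- xr
      fw <- fr
    } else {
      xc <- (b + w) / 2
      fc <- f(xc)
      evals <- evals + 1L
      if (fc < fb) {
        w <- b
        fw <- fb
        b <- xc
        fb <- fc
      } else {
        w <- xc
        fw <- fc
      }
    }
  }
  list(x = b, f = fb, evals = evals, width = abs(b - w))
}

#' Reconstruct the pore-opening trajectory from a current spike
#'
#' The sequential finite-element-style simulation algorithm: the forward
#' model is initialised with the lumen content implied by the spike charge,
#' then [fit_step()] estimates one pore-radius knot per current sample, in
#' order, each search starting from the previously fitted knot.  The
#' resulting piecewise-linear R_p(t) is summarised by its maximum radius
#' `R_p,max` and the 5--95% expansion time `t_expa`.
#'
#' @param spike A spike tibble (`time`, `current`), baseline-subtracted and
#'   uniformly sampled (see [baseline_subtract()] / [as_spike()]).  An
#'   attribute `baseline_sd`, if present, sets the noise floor at three
#'   standard deviations.
#' @param vesicle_radius Vesicle radius (m) from the resistive-pulse
#'   measurement.
#' @param q Spike charge (C); defaults to the trapezoidal charge of the
#'   spike itself.
#' @param config A [recon_config()].
#' @param geometry Optional [vesicle_geometry()]; defaults to
#'   `vesicle_geometry(vesicle_radius)`.
#' @param transport A [transport_params()].
#' @return A `pore_reconstruction` object: the fitted trajectory, per-step
#'   residuals and flags, `r_p_max`, `t_expa`, and the fit RMS.  Use
#'   [tidy()] for the per-step table and [glance()] for the one-row summary.
#' @examples
#' \donttest{
#' geom <- vesicle_geometry(150e-9)
#' truth <- logistic_trajectory(15e-9, 1e-3, 0.3e-3, 4e-3)
#' syn <- synth_spike(truth, q = 0.3e-12,
#'   geometry = geom, noise_sd_frac = 0, backend = "quasi-steady"
#' )
#' fit <- reconstruct_pore_trajectory(syn$spike, 150e-9, q = 0.3e-12)
#' glance(fit)
#' }
#' @export
reconstruct_pore_trajectory <- function(spike, vesicle_radius, q = NULL,
                                        config = recon_config(),
                                        geometry = NULL,
                                        transport = transport_params()) {
  if (nrow(spike) < 3) {
    abort("spike must have at least 3 samples", class = "poretrace_validation_error")
  }
  check_uniform(spike$time)
  if (is.null(geometry)) geometry <- vesicle_geometry(vesicle_radius)
  if (is.null(q)) q <- released_charge(spike)
  if (vesicle_radius <= 0 || q <= 0) {
    abort("vesicle_radius and q must be > 0", class = "poretrace_validation_error")
  }
  bsd <- attr(spike, "baseline_sd")
  noise_floor <- if (is.null(bsd)) 0 else 3 * bsd
  dt <- spike$time[2] - spike$time[1]
  times <- spike$time - spike$time[1]
  n_fit <- length(times) - 1L

  state <- fesa_init(geometry, transport, q, config)
  bounds <- c(config$lower_bound, config$upper_factor * vesicle_radius)
  radii <- numeric(n_fit)
  flags <- character(n_fit)
  fitted <- numeric(n_fit)
  resid <- numeric(n_fit)
  relfrac <- numeric(n_fit)
  nF <- transport$n_electrons * transport$faraday
  overrun <- FALSE
  for (k in seq_len(n_fit)) {
    step <- fit_step(state, spike$current[k + 1],
      bounds = bounds,
      tolerance = config$tolerance, noise_floor = noise_floor, span = dt
    )
    state <- step$state
    radii[k] <- step$radius
    flags[k] <- step$flag
    fitted[k] <- step$fitted_current
    resid[k] <- step$residual
    relfrac[k] <- state$released_frac
    if (flags[k] == "ok" && state$released_frac >= config$depletion_cutoff) {
      flags[k] <- "depleted"
    }
    if (!overrun && state$released_frac > 1.05) {
      overrun <- TRUE
      warn("cumulative simulated charge exceeds 1.05 * Q; continuing")
    }
  }
  if (config$monotone) radii <- cummax(radii)

  traj <- pore_trajectory(times, c(config$initial_radius, radii))
  feats <- pore_features(traj)
  ok <- flags == "ok"
  steps <- tibble(
    time = times[-1], radius = radii, flag = flags,
    target = spike$current[-1], fitted = fitted, residual = resid,
    released_fraction = relfrac
  )
  structure(
    list(
      trajectory = traj, steps = steps,
      r_p_max = feats$r_p_max, t_expa = feats$t_expa,
      fit_rms = if (any(ok)) sqrt(mean(resid[ok]^2)) else NA_real_,
      vesicle_radius = vesicle_radius, q = q, c0 = state$c0,
      noise_floor = noise_floor, backend = config$backend, config = config
    ),
    class = "pore_reconstruction"
  )
}

check_uniform <- function(time, jitter = 1e-9) {
  d <- diff(time)
  if (length(d) == 0 || any(abs(d - d[1]) > jitter)) {
    abort("spike must be uniformly sampled", class = "poretrace_validation_error")
  }
  invisible(time)
}

#' @export
print.pore_reconstruction <- function(x, ...) {
  cat("<pore_reconstruction> (", x$backend, " backend)\n", sep = "")
  cat(sprintf(
    "  %d fitted knots, R_p,max = %.2f nm, t_expa = %.3f ms\n",
    nrow(x$steps), x$r_p_max * 1e9, x$t_expa * 1e3
  ))
  cat(sprintf(
    "  fit RMS = %.3g pA, flags: %s\n", x$fit_rms * 1e12,
    paste(names(table(x$steps$flag)), table(x$steps$flag), sep = ":", collapse = " ")
  ))
  invisible(x)
}

#' Closed-form quasi-steady inversion of a spike
#'
#' Fast independent oracle for [reconstruct_pore_trajectory()]: at each
#' sample the lumped mass balance `(N/V)/R_diff(r) = I/(nF)` is solved for
#' the pore radius by bisection, with the lumen content `N` depleted by the
#' running trapezoidal integral of `I/(nF)`.  No sequential simulation is
#' involved, so the result is an algorithmically independent estimate of
#' the same trajectory.
#'
#' @inheritParams reconstruct_pore_trajectory
#' @param upper_factor Upper radius bound as a fraction of the vesicle
#'   radius; samples demanding more are clipped and flagged.
#' @return A `pore_trajectory` tibble with an extra `flag` column
#'   (`"ok"`, `"nonpositive"`, `"clipped"`, `"depleted"`).
#' @export
quasi_steady_reconstruct <- function(spike, vesicle_radius, q = NULL,
                                     geometry = NULL,
                                     transport = transport_params(),
                                     upper_factor = 0.8) {
  if (nrow(spike) < 3) {
    abort("spike must have at least 3 samples", class = "poretrace_validation_error")
  }
  check_uniform(spike$time)
  if (is.null(geometry)) geometry <- vesicle_geometry(vesicle_radius)
  if (is.null(q)) q <- released_charge(spike)
  nF <- transport$n_electrons * transport$faraday
  vol <- (4 / 3) * pi * vesicle_radius^3
  N0 <- q / nF
  times <- spike$time - spike$time[1]
  n <- length(times)
  ub <- upper_factor * vesicle_radius
  radii <- numeric(n)
  flags <- character(n)
  cum <- c(0, cumsum(diff(times) * (utils::head(spike$current, -1) +
    utils::tail(spike$current, -1)) / 2)) / nF
  for (k in seq_len(n)) {
    I_k <- spike$current[k]
    N_k <- N0 - cum[k]
    if (I_k <= 0) {
      radii[k] <- 0
      flags[k] <- "nonpositive"
      next
    }
    if (N_k <= 0) {
      radii[k] <- ub
      flags[k] <- "depleted"
      next
    }
    gfun <- function(r) {
      (N_k / vol) / diffusive_resistance(r, geometry, transport) - I_k / nF
    }
    if (gfun(ub) < 0) {
      radii[k] <- ub
      flags[k] <- "clipped"
      next
    }
    radii[k] <- stats::uniroot(gfun, c(1e-13, ub), tol = 1e-14)$root
    flags[k] <- "ok"
  }
  new_tibble(
    list(time = times, radius = radii, flag = flags),
    class = "pore_trajectory"
  )
}
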