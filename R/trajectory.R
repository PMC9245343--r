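#' Pore-radius trajectory R_p(t)
#'
#' The object the inverse algorithm estimates: pore radius versus time as a
#' piecewise-linear interpolation through a series of knots.  Stored as a
#' tibble with columns `time` (s, strictly increasing, starting at 0) and
#' `radius` (m, non-negative).
#'
#' @param time Numeric vector of knot times (s), strictly increasing,
#'   starting at 0.
#' @param radius Numeric vector of pore radii (m), same length, all >= 0.
#' @return A `pore_trajectory` tibble.
#' @examples
#' traj <- pore_trajectory(c(0, 1e-4, 2e-4), c(1e-10, 5e-9, 1e-8))
#' pore_radius_at(traj, 1.5e-4)
#' @export
pore_trajectory <- function(time, radius) {
  if (length(time) != length(radius) || length(time) < 1) {
    abort("`time` and `radius` must be equal-length, non-empty",
      class = "poretrace_validation_error"
    )
  }
  if (any(!is.finite(time)) || any(!is.finite(radius))) {
    abort("trajectory knots must be finite", class = "poretrace_validation_error")
  }
  if (time[1] != 0 || any(diff(time) <= 0)) {
    abort("knot times must start at 0 and be strictly increasing",
      class = "poretrace_validation_error"
    )
  }
  if (any(radius < 0)) {
    abort("pore radii must be >= 0", class = "poretrace_validation_error")
  }
  new_tibble(list(time = as.numeric(time), radius = as.numeric(radius)),
    class = "pore_trajectory"
  )
}

#' Evaluate a pore trajectory at arbitrary times
#'
#' Linear interpolation between the bracketing knots; exact knot values at
#' knot times.  Times outside the trajectory domain are an error.
#'
#' @param traj A [pore_trajectory()].
#' @param t Numeric vector of times (s) within `[0, max(traj$time)]`.
#' @return Pore radii (m) at `t`.
#' @export
pore_radius_at <- function(traj, t) {
  tmax <- traj$time[nrow(traj)]
  if (any(t < 0) || any(t > tmax)) {
    abort(sprintf("t outside trajectory domain [0, %g]", tmax),
      class = "poretrace_domain_error"
    )
  }
  if (nrow(traj) == 1) {
    return(rep(traj$radius, length(t)))
  }
  approx(traj$time, traj$radius, xout = t, method = "linear", ties = "ordered")$y
}

#' Maximum pore radius and 5--95% expansion time of a trajectory
#'
#' `R_p,max` is the largest radius; `t_expa` is the time between the first
#' upward crossings of 5% and 95% of `R_p,max`, with crossing times located
#' by linear interpolation between knots.  For a trajectory that starts at
#' or above 95% of its maximum (e.g. a constant), `t_expa` is 0.
#'
#' @param traj A [pore_trajectory()] (any tibble with `time` and `radius`).
#' @return One-row tibble with columns `r_p_max` (m) and `t_expa` (s).
#' @examples
#' ramp <- pore_trajectory(c(0, 2e-3, 4e-3), c(0, 20e-9, 20e-9))
#' pore_features(ramp) # t_expa = 1.8 ms
#' @export
pore_features <- function(traj) {
  if (nrow(traj) < 1) {
    abort("trajectory is empty", class = "poretrace_validation_error")
  }
  r_max <- max(traj$radius)
  if (r_max <= 0) {
    return(tibble(r_p_max = 0, t_expa = NA_real_))
  }
  t05 <- first_upward_crossing(traj$time, traj$radius, 0.05 * r_max)
  t95 <- first_upward_crossing(traj$time, traj$radius, 0.95 * r_max)
  tibble(r_p_max = r_max, t_expa = t95 - t05)
}

## first time the piecewise-linear curve reaches `level` from below; if the
## curve starts at or above `level`, returns the first time point.
first_upward_crossing <- function(time, value, level) {
  if (value[1] >= level) {
    return(time[1])
  }
  above <- which(value >= level)
  if (length(above) == 0) {
    return(NA_real_)
  }
  k <- above[1]
  t0 <- time[k - 1]
  t1 <- time[k]
  v0 <- value[k - 1]
  v1 <- value[k]
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}

## last upward crossing of `level` at or before index `before` (used for
## rise times, guarding against noise re-crossings near the baseline).
last_upward_crossing_before <- function(time, value, level, before) {
  idx <- seq_len(before)
  below <- value[idx] < level
  ## segments k -> k+1 that cross upward
  cross <- which(below[-length(idx)] & !below[-1])
  if (length(cross) == 0) {
    return(if (value[1] >= level) time[1] else NA_real_)
  }
  k <- cross[length(cross)]
  t0 <- time[k]
  t1 <- time[k + 1]
  v0 <- value[k]
  v1 <- value[k + 1]
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}
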