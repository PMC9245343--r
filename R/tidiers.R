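#' Tidy the per-step table of a pore reconstruction
#'
#' @param x A `pore_reconstruction` from [reconstruct_pore_trajectory()].
#' @param ... Unused.
#' @return Tibble with one row per fitted knot: `time`, `radius`, `flag`,
#'   `target`, `fitted`, `residual`, `released_fraction`.
#' @method tidy pore_reconstruction
#' @export
tidy.pore_reconstruction <- function(x, ...) {
  x$steps
}

#' One-row summary of a pore reconstruction
#'
#' @inheritParams tidy.pore_reconstruction
#' @return One-row tibble: `r_p_max` (m), `t_expa` (s), `fit_rms` (A),
#'   `n_steps`, `n_flagged`, `backend`, `q` (C), `c0` (mol/m^3).
#' @method glance pore_reconstruction
#' @export
glance.pore_reconstruction <- function(x, ...) {
  tibble(
    r_p_max = x$r_p_max, t_expa = x$t_expa, fit_rms = x$fit_rms,
    n_steps = nrow(x$steps), n_flagged = sum(x$steps$flag != "ok"),
    backend = x$backend, q = x$q, c0 = x$c0
  )
}

#' Coefficient table of a log-log scaling fit
#'
#' @param x A `loglog_fit` from [loglog_scaling_fit()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error` for the intercept
#'   and slope of the log10-log10 regression.
#' @method tidy loglog_fit
#' @export
tidy.loglog_fit <- function(x, ...) {
  sm <- summary(attr(x, "model"))$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(sm[, 1]),
    std_error = unname(sm[, 2])
  )
}

#' One-row summary of a log-log scaling fit
#'
#' @inheritParams tidy.loglog_fit
#' @return The fit's own one-row tibble (`slope`, `intercept`, `pearson_r`,
#'   `n`) plus the regression `r_squared`.
#' @method glance loglog_fit
#' @export
glance.loglog_fit <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, pearson_r = x$pearson_r,
    n = x$n, r_squared = summary(attr(x, "model"))$r.squared
  )
}
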