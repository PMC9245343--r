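#' Construct a spike object from time/current samples
#'
#' A spike is a baseline-subtracted amperometric current transient from one
#' vesicle release event, uniformly sampled (0.1 ms in the VIEC protocol).
#'
#' @param time Sample times (s), uniformly spaced (jitter tolerance 1 ns).
#' @param current Baseline-subtracted currents (A).
#' @param baseline_sd Standard deviation of the pre-spike baseline (A);
#'   used to derive noise floors for identifiability flags.
#' @param metadata Optional named list (vesicle id, R_ves, ...).
#' @return A `spike` tibble.
#' @export
as_spike <- function(time, current, baseline_sd = 0, metadata = list()) {
  if (length(time) != length(current) || length(time) < 1) {
    abort("time and current must be equal-length, non-empty",
      class = "poretrace_validation_error"
    )
  }
  if (any(!is.finite(time)) || any(!is.finite(current))) {
    abort("spike samples must be finite", class = "poretrace_validation_error")
  }
  if (length(time) > 1) check_uniform(time)
  out <- new_tibble(list(time = as.numeric(time), current = as.numeric(current)),
    class = "spike"
  )
  attr(out, "baseline_sd") <- baseline_sd
  attr(out, "metadata") <- metadata
  out
}

#' Subtract the pre-spike baseline from a raw trace
#'
#' Subtracts the mean current over the pre-spike window and records the
#' window's standard deviation as `baseline_sd` (the basis of the
#' 3-sigma noise floor used downstream).
#'
#' @param trace A tibble with `time` (s) and `current` (A) columns (raw,
#'   uniformly sampled).
#' @param pre_end End of the baseline window (s); the window is
#'   `[pre_start, pre_end]` and must precede the spike onset.
#' @param pre_start Start of the baseline window; defaults to the first
#'   sample.
#' @return A [as_spike()] object covering the samples after `pre_end`.
#' @export
baseline_subtract <- function(trace, pre_end, pre_start = min(trace$time)) {
  win <- trace$time >= pre_start & trace$time <= pre_end
  if (!any(win)) {
    abort("baseline window contains no samples", class = "poretrace_validation_error")
  }
  mu <- mean(trace$current[win])
  sdev <- if (sum(win) > 1) sd(trace$current[win]) else 0
  keep <- trace$time > pre_end
  if (!any(keep)) keep <- rep(TRUE, nrow(trace))
  as_spike(trace$time[keep], trace$current[keep] - mu, baseline_sd = sdev)
}

#' Scalar features of a current spike
#'
#' Peak current `i_max` and its time `t_max`, trapezoidal charge `q`, and
#' the 5--95% rise time `t_rise`: the time from the last upward crossing of
#' `0.05 * i_max` before the first upward crossing of `0.95 * i_max`
#' (crossings located by linear interpolation between samples; taking the
#' *last* 5% crossing guards against baseline-noise re-crossings).
#'
#' @param spike An [as_spike()] tibble.
#' @return One-row tibble: `i_max` (A), `t_max` (s), `q` (C), `t_rise` (s);
#'   `t_rise` is `NA` when a crossing cannot be located.
#' @examples
#' s <- as_spike(seq(0, 1e-3, 1e-4), c(seq(0, 1e-11, length.out = 10), 0))
#' spike_features(s)
#' @export
spike_features <- function(spike) {
  i_max <- max(spike$current)
  k_max <- which.max(spike$current)
  bsd <- attr(spike, "baseline_sd")
  if (!is.null(bsd) && i_max <= 5 * bsd) {
    warn("spike maximum is not above 5 x baseline SD")
  }
  t95 <- first_upward_crossing(spike$time, spike$current, 0.95 * i_max)
  t_rise <- NA_real_
  if (!is.na(t95)) {
    before <- which(spike$time >= t95)[1]
    t05 <- last_upward_crossing_before(
      spike$time, spike$current,
      0.05 * i_max, before
    )
    if (!is.na(t05)) t_rise <- t95 - t05
  }
  tibble(
    i_max = i_max, t_max = spike$time[k_max],
    q = released_charge(spike), t_rise = t_rise
  )
}

#' Classify the spike decay as single-exponential
#'
#' Fits `I(t) = A exp(-(t - t_max)/tau)` on the falling portion (from the
#' peak to the first sample below 5% of the peak) by least squares in log
#' space on the positive samples.  Spikes whose decay is well described by
#' a single exponential (high log-space R^2) are classified as
#' nondense-core vesicles -- the subset the uniform-lumen release model
#' applies to; dense-core vesicles show two-phase decays and are excluded.
#'
#' @param spike An [as_spike()] tibble.
#' @param r2_threshold Minimum R^2 for the `nondense_core` call
#'   (default 0.95).
#' @return One-row tibble: `tau` (s), `r_squared`, `nondense_core`
#'   (logical).  All `NA` when the falling portion has fewer than 5 usable
#'   samples or nonpositive samples dominate.
#' @export
classify_decay <- function(spike, r2_threshold = 0.95) {
  i_max <- max(spike$current)
  k_max <- which.max(spike$current)
  tail_idx <- seq(k_max, nrow(spike))
  below <- which(spike$current[tail_idx] < 0.05 * i_max)
  if (length(below) > 0) tail_idx <- tail_idx[seq_len(below[1] - 1)]
  t <- spike$time[tail_idx]
  y <- spike$current[tail_idx]
  pos <- y > 0
  if (length(tail_idx) < 5 || mean(pos) < 0.5) {
    return(tibble(tau = NA_real_, r_squared = NA_real_, nondense_core = NA))
  }
  fit <- lm(log(y[pos]) ~ t[pos])
  slope <- unname(coef(fit)[2])
  ## summary.lm warns on an exactly exponential input; that case is valid here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(
    tau = if (slope < 0) -1 / slope else NA_real_,
    r_squared = r2,
    nondense_core = r2 >= r2_threshold
  )
}
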