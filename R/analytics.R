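#' Maximum pore radius under the membrane-section model
#'
#' Phenomenological picture of electroporation in the vesicle-electrode
#' contact region: membrane proteins partition the contact area
#' \eqn{S_c = k_d S_{ves}} into small sections, each of which electroporates
#' irreversibly with probability `p_e`; the expected total pore area is
#' \eqn{S_{p,max} = p_e k_d S_{ves}} with \eqn{S_{ves} = 4\pi R_{ves}^2}.
#' Equating \eqn{S_{p,max} = \pi R_{p,max}^2} gives
#' \deqn{R_{p,max} = 2 R_{ves} \sqrt{p_e k_d}.}
#'
#' @param vesicle_radius Vesicle radius (m), vectorised.
#' @param p_e Electroporation probability per membrane section, in
#'   `[0, 1]`.
#' @param k_d Deformation coefficient (contact area as a fraction of the
#'   vesicle surface), in `(0, 1]`.
#' @return Maximum pore radius (m).  `p_e * k_d` above 0.25 would imply a
#'   pore larger than the vesicle and is a validation error.
#' @examples
#' section_model_pore_radius(150e-9, p_e = 0.01, k_d = 0.25) # 15 nm
#' @export
section_model_pore_radius <- function(vesicle_radius, p_e, k_d) {
  if (any(p_e < 0) || any(p_e > 1) || any(k_d <= 0) || any(k_d > 1)) {
    abort("p_e must be in [0, 1] and k_d in (0, 1]", class = "poretrace_domain_error")
  }
  if (any(p_e * k_d > 0.25)) {
    abort("p_e * k_d > 0.25 would imply R_p,max > R_ves",
      class = "poretrace_validation_error"
    )
  }
  2 * vesicle_radius * sqrt(p_e * k_d)
}

#' Log-log scaling of maximum pore radius versus vesicle radius
#'
#' Ordinary least squares of `log10(r_p_max)` on `log10(r_ves)` over a
#' population of vesicles, plus the Pearson correlation of the log-log
#' pairs.  A population obeying the membrane-section model with constant
#' `p_e * k_d` has slope 1; steeper slopes mean the pore/vesicle size ratio
#' itself grows with vesicle size.
#'
#' @param records Tibble with columns `r_ves` and `r_p_max` (m), radii > 0,
#'   at least 3 rows.
#' @return A one-row `loglog_fit` tibble: `slope`, `intercept` (log10 m),
#'   `pearson_r`, `n`.  The underlying `lm` fit and data are attached as
#'   attributes; [tidy()] returns the coefficient table.
#' @export
loglog_scaling_fit <- function(records) {
  if (nrow(records) < 3) {
    abort("need at least 3 records", class = "poretrace_validation_error")
  }
  if (any(records$r_ves <= 0) || any(records$r_p_max <= 0)) {
    abort("radii must be > 0", class = "poretrace_domain_error")
  }
  x <- log10(records$r_ves)
  y <- log10(records$r_p_max)
  if (sd(x) == 0) {
    abort("zero variance in r_ves", class = "poretrace_validation_error")
  }
  fit <- lm(y ~ x)
  out <- new_tibble(
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      pearson_r = stats::cor(x, y), n = nrow(records)
    ),
    class = "loglog_fit"
  )
  attr(out, "model") <- fit
  attr(out, "data") <- tibble(log10_r_ves = x, log10_r_p_max = y)
  out
}

#' Pore/vesicle size ratio versus vesicle size
#'
#' @param records Tibble with columns `r_ves` and `r_p_max` (m).
#' @return Tibble with `r_ves` and `ratio` (`r_p_max / r_ves`).
#' @export
ratio_vs_size <- function(records) {
  if (nrow(records) == 0) {
    return(tibble(r_ves = numeric(0), ratio = numeric(0)))
  }
  if (any(records$r_ves <= 0)) {
    abort("radii must be > 0", class = "poretrace_domain_error")
  }
  tibble(r_ves = records$r_ves, ratio = records$r_p_max / records$r_ves)
}

#' Mann-Whitney U test (two-tailed)
#'
#' Rank-sum comparison of two independent groups, as used to compare pore
#' expansion times of vesicles and protein-free liposomes.  For group sizes
#' up to 8 the null distribution of U is enumerated exactly over all
#' arrangements of the pooled sample (ties handled by midranks), and the
#' two-tailed p-value is the probability of a U at least as far from
#' `n1 n2 / 2` as observed.  For larger groups a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param group_a,group_b Numeric vectors, non-empty.
#' @return One-row tibble: `u` (U statistic of `group_a`), `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty", class = "poretrace_validation_error")
  }
  n1 <- length(group_a)
  n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  centre <- n1 * n2 / 2
  if (max(n1, n2) <= 8) {
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(rk[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
    method <- "exact"
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    z <- if (sigma2 > 0) {
      (u_obs - centre - sign(u_obs - centre) * 0.5) / sqrt(sigma2)
    } else {
      0
    }
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  tibble(u = u_obs, p_value = p, method = method)
}
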