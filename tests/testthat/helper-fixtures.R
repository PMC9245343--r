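## shared fixtures: small geometries and a cheap mesh configuration for the
## PDE tests (tests that assert convergence refine from this baseline)

std_geometry <- function(r_ves = 150e-9) vesicle_geometry(r_ves)

coarse_config <- function(...) {
  sim_config(cell_near_pore = 0.6e-9, growth_fine = 1.12, ...)
}

## brute-force Mann-Whitney oracle: enumerate all assignments of the pooled
## sample, U computed from midranks, two-tailed tail probability around
## n1 n2 / 2
mw_enumerate <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  centre <- n1 * length(b) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  list(u = u_obs, p = mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9))
}
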