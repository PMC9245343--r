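# poretrace

Membrane pore-opening dynamics of single nanometre vesicles, reconstructed
from amperometric current spikes.

## The problem

In vesicle impact electrochemical cytometry (VIEC), a single vesicle lands
on a polarised carbon-fibre microelectrode, electroporates, and its
catecholamine content diffuses out through the membrane pore and is
oxidised on contact. The measured current spike `I(t)` encodes the pore
dynamics: the total charge `Q` fixes the content by Faraday's law
(`C_0 = Q / (nF · (4/3)πR_ves³)`, `n = 2`), while the *shape* of the spike
is gated by the time-dependent pore radius `R_p(t)`. Given `R_ves` from a
resistive-pulse measurement and the spike, `poretrace` solves the inverse
problem: which pore trajectory produced this spike?

The package is aimed at single-entity electrochemists and membrane
biophysicists. It provides:

* **Forward model** — axisymmetric diffusion (Fick's second law,
  `D_in = 6e-11`, `D_out = 6e-10` m²/s) from a spherical lumen through a
  5 nm pore channel and a 20 nm gap onto an absorbing microdisk, solved by
  a conservative finite-volume scheme with backward-Euler stepping
  (`simulate_current()`), plus a lumped quasi-steady oracle built on the
  access-resistance sum
  `R_diff(r) = 1/(4D_in r) + L/(D_out πr²) + 1/(4D_out r)`
  (`quasi_steady_current()`).
* **Sequential reconstruction** — one pore-radius knot per 0.1 ms sample,
  each found by a bounded one-dimensional Nelder–Mead fit of the simulated
  to the measured current (search zone `1e-11` m to `0.8·R_ves`, argument
  tolerance `1e-11` m), with identifiability flags for noise-floor,
  clipped, and post-depletion samples (`reconstruct_pore_trajectory()`),
  cross-checked by a closed-form quasi-steady inversion
  (`quasi_steady_reconstruct()`).
* **Spike analysis** — baseline subtraction, peak/charge/5–95% rise time,
  single-exponential decay classification (nondense-core filter)
  (`spike_features()`, `classify_decay()`).
* **Population analytics** — log-log scaling of `R_p,max` vs `R_ves`, the
  membrane-section model `R_p,max = 2 R_ves √(p_e k_d)`, and an exact
  Mann–Whitney test (`loglog_scaling_fit()`, `section_model_pore_radius()`,
  `mann_whitney_u()`).
* **Synthetic data** — logistic pore trajectories, noisy forward-simulated
  spikes, and study-scale populations for closed-loop validation
  (`synth_spike()`, `synth_population()`).

Everything takes and returns tibbles, chains with the pipe, and fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Synthesise a spike from a known logistic pore trajectory (plateau 20 nm,
midpoint 0.8 ms, 2% peak noise) on a 150 nm vesicle carrying 0.5 pC, then
reconstruct the trajectory from the spike alone:

```r
library(poretrace)

geom  <- vesicle_geometry(150e-9)
truth <- logistic_trajectory(20e-9, t_mid = 0.8e-3, steepness = 0.25e-3, t_end = 3e-3)
syn   <- synth_spike(truth, q = 0.5e-12, geom, noise_sd_frac = 0.02, seed = 1)

fit <- reconstruct_pore_trajectory(syn$spike, 150e-9, q = 0.5e-12)
fit
#> <pore_reconstruction> (quasi-steady backend)
#>   30 fitted knots, R_p,max = 20.78 nm, t_expa = 1.515 ms
#>   fit RMS = 0.0138 pA, flags: ok:29 unidentifiable:1

pore_features(truth)
#> # A tibble: 1 x 2
#>        r_p_max  t_expa
#> 1 0.0000000200 0.00148
```

The reconstruction recovers the 20 nm plateau within 4% and the 1.48 ms
expansion time within ~3% despite the noise; the one `unidentifiable` flag
marks the first sample, whose current sits below the 3σ noise floor.
`autoplot(fit)` plots the fitted knots coloured by flag;
`spike_features(syn$spike)` returns the peak (117 pA at 1.4 ms), the
trapezoidal charge, and the 5–95% rise time (1.25 ms, tracking the
trajectory's expansion time). Passing
`config = recon_config(backend = "full-pde")` runs the same sequential fit
against the full finite-volume solver instead of the lumped model.

A thin command-line wrapper over the same functions ships in
`inst/cli/poretrace.R` (subcommands `simulate`, `reconstruct`, `features`,
`scaling`, `synth`; TSV/JSON interchange in SI units).

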