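# nmrdecon

Bayesian spectral deconvolution of one-dimensional ¹⁹F NMR spectra.

Protein NMR in living cells — for example ¹⁹F spectra of
trifluoromethoxy-labelled H-Ras delivered into HeLa cells — produces broad,
weak resonances close to the noise floor. The scientific questions are *how
many* signals the spectrum contains (distinct conformational states) and
what each signal's area, chemical shift, and linewidth are, with honest
uncertainties. Eyeballing peaks or least-squares fitting with a guessed peak
count cannot answer the first question; `nmrdecon` answers both with
Bayesian model selection.

## The model

After standard preprocessing the data are `D = {x_n, y_n}`, `N = 8192` real
intensities on a ppm axis with known white-Gaussian noise level σ estimated
from the FID tail. Each of K signals is an absorptive Lorentzian with
parameters θₖ = (Mₖ, ωₖ, βₖ) — area (a.u.), shift (ppm), and log₁₀ FWHM
(Hz) — under uniform box priors (M ∈ [0, 700], ω ∈ [−62, −55] ppm,
β ∈ [1, 4]). For each K ∈ {0, …, K_max} the Bayes free energy
F(K) = −log evidence is computed by thermodynamic integration,
F(K) = −∫₀¹ E_β[log L] dβ, over a geometric inverse-temperature ladder
(46 rungs at production settings) with adaptive-Metropolis chains per rung
and a generalized-ESD screen over chains; then
P(K | D) ∝ exp(−F(K)). At the selected K, a long β = 1 run yields the
posterior; label switching is resolved by anchored relabeling, and results
are reported as MAP estimates with 95% percentile credible intervals.

## Worked example

Simulate a broad single-line spectrum like an in vitro GMPPNP-state
measurement (area 300 a.u., shift −58.4 ppm, FWHM 164.8 Hz, SNR 50) and
deconvolve it end to end with a reduced profile:

```r
library(nmrdecon)

sc  <- nmr_scenarios()$invitro_broad
fid <- simulate_fid(sc$components, sc$acq, seed = 7)

profile <- list(name = "example",
                ladder = build_ladder(8, 0.01),
                tempered = chain_config(6000, 3000, 3, n_chains = 5,
                                        max_outliers = 2),
                posterior = chain_config(60000, 10000, 25, n_chains = 1,
                                         max_outliers = 0))
res <- deconvolve(fid, k_max = 3, profile = profile, seed = 1)
res
#> <nmr_deconvolution>
#>   noise sigma: 13.23 a.u.
#>  K free_energy    posterior
#>  0    42454.30 0.000000e+00
#>  1    32891.54 1.000000e+00
#>  2    33079.96 1.491894e-82
#>  3    33758.41 0.000000e+00
#>   most probable K: 1
#>   component summaries (MAP [95% CI]):
#>  component parameter        map      lower      upper level
#>          1         M 303.459389 297.355396 309.729429    95
#>          1     omega -58.399641 -58.402463 -58.396673    95
#>          1      beta   2.221657   2.208392   2.233022    95
#>          1   fwhm_hz 166.593285 161.581754 171.010219    95
```

Reading the output: the pure-noise model (K = 0) is ruled out by ~9,600
nats of free energy; one component is overwhelmingly preferred over two or
three (P(K=1|D) ≈ 1). The MAP area (303.5 a.u.), shift (−58.400 ppm) and
linewidth (166.6 Hz) recover the simulated truth (300, −58.4, 164.8) with
the truth inside every 95% credible interval. `autoplot(res)` overlays the
final MAP model on the observed spectrum, both shown with the conventional
200 Hz display apodization; `tidy(res)` returns the summary table and
`glance(res)` the selection headline.

The full-scale protocol (46-rung ladder, 19 chains, 10⁸-step posterior run)
is available as `profile = "paper"`; `profile = "desk"` (the default) is a
scaled-down setting for interactive work.

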