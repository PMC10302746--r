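---
title: "Bayesian deconvolution of low-SNR 19F NMR spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian deconvolution of low-SNR 19F NMR spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

One-dimensional ¹⁹F NMR of fluorine-labelled proteins inside live cells asks
a hard statistical question of very noisy data: *how many* resonances are
present, and what are their areas, shifts, and linewidths? In-cell lines are
broad (hundreds to thousands of Hz) and sit near the noise floor, so visual
peak counting and least-squares fitting with a hand-chosen number of peaks
are unreliable. `nmrdecon` treats the question as Bayesian model selection:
each candidate number of components K gets a Bayes free energy (minus log
evidence), and the posterior over K follows from those free energies.

## Signal model

After preprocessing, the data are `D = {x_n, y_n}`, `n = 1..N` with
`N = 8192`: real intensities on a referenced, descending ppm axis. Each of
the K signals is an absorptive Lorentzian parameterized by
`theta_k = (M_k, omega_k, beta_k)`:

* `M_k` — the peak **area** (macroscopic magnetization) in arbitrary units,
* `omega_k` — the chemical shift in ppm,
* `beta_k` — the common logarithm of the full width at half maximum in Hz.

With `gamma_k = 10^beta_k / nu_0` the FWHM in ppm at spectrometer frequency
`nu_0` (MHz),

```
f_k(x) = (M_k / pi) * (gamma_k / 2) / ((x - omega_k)^2 + (gamma_k / 2)^2),
```

and the model spectrum is `F(x) = sum_k f_k(x)`; `K = 0` is the pure-noise
model. Because no apodization is applied before fitting and thermal noise
dominates, the spectral noise is white Gaussian with a *known* standard
deviation `sigma` (see below), giving the log likelihood

```
log L(D | theta, K) = sum_n [ -1/2 log(2 pi sigma^2)
                              - (y_n - F(x_n))^2 / (2 sigma^2) ].
```

Priors are independent uniforms on a box: `M` in [0, 700] a.u., `omega` in
[−62, −55] ppm, `beta` in [1, 4] (FWHM 10–10,000 Hz). The box is
configurable; these defaults suit ¹⁹F spectra of OCF₃-labelled proteins
referenced to TFA. `sigma` is a plug-in estimate, not a sampled parameter —
the tail of the FID measures it directly, and fixing it keeps the evidence
comparison across K on one common noise model.

## Preprocessing

`preprocess_fid()` chains the standard steps:

1. **Digital-filter removal.** The group delay's integer part is undone by a
   circular sample shift, the fractional part by a frequency-domain linear
   phase ramp. FID length is preserved.
2. **Truncation and zero-filling.** The first 4096 complex points (30.6 ms
   at 565 MHz / 237 ppm) are kept and zero-filled to 8192. The signals this
   package targets have decayed within that window; the rest of the FID is
   noise and is reserved for estimating `sigma`.
3. **Fourier transform, no apodization.** Unnormalized DFT; the real part on
   a descending ppm axis (spacing `sweep / N`) is the fitted intensity.
4. **Baseline correction.** A 4th-order polynomial is fitted by iterative
   reweighting: points more than 3 running standard deviations *above* the
   current fit are excluded and the fit repeated (at most 10 rounds), so
   positive peaks do not drag the baseline. Whether the original analysis
   excluded peak points is not something the procedure name pins down; the
   robust scheme is this package's choice, and the peak-preservation
   property is tested (a narrow line on a quartic baseline keeps its area
   within 2%).
5. **Noise estimation.** With per-quadrature time-domain SD `sigma_t`
   measured from the FID after 30.6 ms, and `n_keep` points entering the
   unnormalized DFT, each spectral bin's real part has variance
   `n_keep * sigma_t^2`; the package uses `sigma = sqrt(n_keep) * sigma_t`.
   This time-to-frequency bridge is locked by a Monte-Carlo test. The tail
   is taken from the filter-corrected FID (the correction is unitary, so
   this choice is immaterial for white noise).

No phase correction is applied anywhere: the pipeline's contract is
zero-phase (purely absorptive) data, and the simulator emits exactly that.
Mixed-phase data are out of contract.

## Model-order selection

For each K the Bayes free energy `F(K) = -log integral prior * likelihood`
is computed by thermodynamic integration over a geometric inverse-temperature
ladder `0 = beta_0 < beta_1 < ... < beta_J = 1`:

```
F(K) = - integral_0^1 E_beta[ log L ] d beta,
```

approximated with the trapezoidal rule (the quadrature rule is this
package's choice). The production ladder has `J = 45`, `beta_1 = 0.01`, a
constant ratio `beta_{j-1}/beta_j = 0.9006`, 46 rungs in all. At each
positive rung, independent adaptive random-walk Metropolis chains target
`prior * likelihood^beta`; at `beta = 0` that target *is* the prior, so the
package draws i.i.d. prior samples there instead of running a chain — exact
and free of mixing error. `K = 0` has no parameters, so `F(0)` is the
closed-form negative log likelihood of the zero model.

The per-rung expectation pools equal-weight per-chain means of `log L` over
retained samples, after a two-sided generalized extreme Studentized deviate
(gESD) screen drops up to `max_outliers` chains per rung (production: at
most 9 of 19) — chains trapped in local modes report systematically low
means, and the screen is what makes random multistart viable. Pooling
per-chain means with equal weights (rather than pooling raw draws first) is
the package's reading of the protocol and is documented as an assumption.

`P(K | D) ∝ exp(-F(K))` under a uniform prior over `K = 0..K_max`
(default `K_max = 3`), normalized with log-sum-exp.

## Sampler

The proposal is Gaussian random walk whose covariance adapts during burn-in
(Haario-style: running sample covariance scaled by `2.38^2 / d`, refreshed
every 100 steps) together with a Robbins–Monro global scale tuned toward a
0.28 acceptance rate; both freeze at the end of burn-in, so the retained
draws come from a fixed Markov kernel. Proposals outside the prior box are
rejected through the prior. Delayed rejection is not implemented — plain
adaptive Metropolis is the variant this package commits to.

Each chain starts at the best of a pool (default 100) of i.i.d. prior draws
scored by the tempered target. This keeps starts random and independent
across chains while making a start inside the dominant basin overwhelmingly
likely. The production protocol instead relies on many chains plus the gESD
screen to absorb failed uniform starts; at desk-scale chain counts (3–5)
that safety margin is too thin, and the pooled start is the package's
robustness choice. With `init_pool = 1` the behaviour reverts to plain
uniform starts.

Reproducibility: one master seed; every (K, rung, chain) sub-run derives its
own seed from it by a fixed integer recursion (kept below 2^31), so any
sub-run can be reproduced in isolation and full pipelines are bit-identical
under a fixed seed.

## Posterior summaries

At the selected K, a long `beta = 1` run (production: 100,050,000 steps,
burn-in 50,000, thinning 200, hence 500,000 retained draws) yields the
posterior sample. The mixture posterior is K!-symmetric, so before
per-component summaries the draws are relabeled by an anchored iteration:
pick a random draw as anchor; repeatedly (a) permute each draw's components
to minimize the standardized Euclidean distance to the anchor, (b) reset the
anchor to the component-wise mean of the relabeled draws; stop at
convergence or 20 iterations. Two details are package choices where the
procedure leaves room: the anchor update is the component-wise mean, and the
per-dimension scales (SD of M, omega, beta pooled over all draws and
components) are computed once from the unrelabeled draws and held fixed, for
determinism. A zero-variance dimension falls back to scale 1 with a warning.

The MAP estimate is the retained draw with the largest unnormalized log
posterior (ties: earliest draw). Credible intervals are equal-tailed
percentiles of the relabeled draws; FWHM intervals are `10^` the `beta`
endpoints, exact because percentiles commute with monotone maps.

For figures only, `render_map_overlay()` rebuilds the model FID from the MAP
parameters and applies a 200 Hz exponential apodization to both model and
observed FIDs before transforming — every Lorentzian gains exactly 200 Hz of
width, which the tests verify. Apodized data are never fitted.

## The simulator

`simulate_fid()` is the generative mirror of the fitted model:

```
s(t) = sum_k a_k exp(2 pi i dnu_k t - pi fwhm_k t + i phase_k) + noise(t),
```

with complex white Gaussian noise of per-quadrature SD `noise_sigma_t`. The
amplitude convention is calibrated so the generative `area` and the fitted
`M` mean the same thing: the unnormalized DFT of a truncated FID sums to
`N * s(0)`, and after the baseline absorbs the constant trapezoid offset the
rendered peak integrates to `a * sweep / 2` on the ppm axis, so
`a = 2 * area / sweep`. The first time-domain point is sampled with full
weight; the calibration absorbs that convention, and a round-trip test
(simulate, preprocess, measure) locks area, shift, and FWHM to grid
resolution. Optional group delays are injected as the exact inverse of the
removal operator.

Scenario presets (`nmr_scenarios()`) emulate the studied regimes: a narrow
27.5 Hz line and a broad 164.8 Hz line (the measured GDP- and GMPPNP-state
widths of the Y32 reporter), a resolvable two-component mixture near
−58 ppm, a broad low-SNR in-cell line, and pure noise. Scenario SNR is
defined as rendered peak height over spectral noise SD; the in-cell value
(4) is a package choice straddling the detection threshold, since true
in-cell SNR is not a published number. The simulator reproduces the
statistical structure the analysis assumes — exponentially decaying
absorptive signals in white Gaussian noise. Real in-cell spectra also carry
baseline roll, residual background ¹⁹F signals, field drift and chemical
exchange; passing tests here demonstrate the inference machinery is correct
under its own assumptions, not that those assumptions exhaust biology.

## Problem sizes used by tests and the acceptance script

The full protocol (46 rungs, 19 chains, 10⁸-step posterior) is available as
`run_profile("paper")` but is not what automated checks run. The package's
own validation sizes, chosen once:

* **Evidence oracle**: N = 256 spectrum, one wide line (3000 Hz), SNR ≈ 2,
  prior box restricted to wide lines (`beta` in [3, 3.7]), desk ladder
  (J = 12) and chains. The restriction matters: near `beta = 0` the
  thermodynamic integrand is dominated by prior mass on narrow large-area
  lines, and a 13-rung trapezoid cannot resolve that spike. On wide-line
  boxes the integrand is smooth and the TI estimate agrees with 120³-cell
  brute-force quadrature to well under 1 nat.
* **Model-order selection**: N = 2048 spectra (keep 1024, zero-fill 2048),
  broad lines (300–400 Hz), SNR 20, ladder J = 8, 5 chains of 6000 steps.
* **Coverage**: 20 replicates of the broad in vitro scenario at full
  N = 8192, single-chain posterior runs of 60,000 steps (2000 retained).
* **Round-trip physics**: full production geometry (65,536-point
  acquisition is reduced to 16,384 simulated points — the fitted 30.6 ms
  window plus a long noise tail — which changes nothing downstream).

## Known limitations

* Lorentzian lineshapes only: no Gaussian/Voigt, no phase or baseline
  nuisance parameters inside the likelihood, no chemical-exchange models.
* The evidence estimate inherits trapezoid bias when the prior box admits
  lines far narrower than the data's; the production ladder (46 rungs) keeps
  this small and constant across K, so selection is unaffected, but absolute
  free energies on wide boxes at coarse ladders should not be over-read.
* `sigma` is treated as known; misestimated noise propagates into both the
  likelihood scale and the evidence.
* Vendor raw formats are not parsed; the native container and the simulator
  are the supported inputs.
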