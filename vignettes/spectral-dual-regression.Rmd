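---
title: "Modelling cardio-respiratory power in fast-TR EPI spectra"
author: "physiodr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardio-respiratory power in fast-TR EPI spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

A fast-TR EPI scan (TR around 0.3 s) samples the brain quickly enough that
the fundamental cardiac frequency (≈ 1 Hz) lies below the Nyquist frequency
`1/(2·TR)`. In the frequency domain, a voxel's one-sided amplitude spectrum
above the neurovascular regime is then well described by three components:
a flat thermal-noise floor, a respiratory spectrum and a cardiac spectrum.
`physiodr` fits, per voxel,

$$P(f) = \alpha \cdot 1 + \beta_r X_r(f) + \beta_c X_c(f) + \varepsilon(f),
  \qquad f \in [f_{min}, 1/(2\,TR)],$$

by ordinary least squares along the frequency dimension, where $P$, $X_r$
and $X_c$ are each normalized to unit sum over the band. The assumptions
are:

* **Additivity in amplitude.** Band amplitudes of the three sources add
  per bin. This ignores phase interference between sources sharing a bin,
  which averages out over many bins and realizations.
* **Flat thermal floor.** White thermal noise contributes a constant
  expected magnitude at every frequency.
* **Stationarity within the scan.** The physiological spectra are treated
  as fixed over the acquisition; slow heart-rate drift spreads mass over
  neighbouring bins but does not break the model.
* **Frequency separation from neurovascular signal.** BOLD fluctuations of
  neurovascular origin are assumed to live below `fmin` = 0.2 Hz and are
  excluded by the band cut, not modelled.

The amplitude (not squared-power) reading of the spectrum is used
throughout: the quantity entering the GLM is $\sqrt{Re^2 + Im^2}$ of the
Fourier transform. `amplitude_spectrum(power = TRUE)` exposes the squared
alternative as a configuration switch; all defaults and downstream
normalizations assume amplitude.

Because all spectra are unit-sum normalized, the coefficients are coupled:
a noiseless voxel satisfies $\alpha N_b + \beta_r + \beta_c = 1$ over $N_b$
band bins. A voxel gaining cardiac power necessarily loses baseline and
respiratory share. Group analyses therefore control the complementary
coefficient as a covariate of no interest (`partial_correlation()`).

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `fmin` | 0.2 | Hz | lower band edge; excludes the neurovascular regime |
| `split_hz` | 0.6 | Hz | data-driven seed split; respiratory below, cardiac above; a bin exactly at the split goes to the respiratory side |
| `tolerance` | 0.01 | L1 | convergence: sum of absolute changes of each refined spectrum between iterations, required for cardiac and respiratory separately |
| `max_iter` | 50 | — | iteration cap; hitting it flags `converged = FALSE` rather than erroring |
| `p_threshold` | 0.01 | — | per-voxel significance for masks, means and extents |
| `pve_threshold` | 0.7 | — | tissue-mask membership, strict `pve > 0.7` |
| `window_hz` | 0.04 | Hz | width of the cardiac pulsatility window |

The defaults are the constants of the fast-TR protocol the package is
designed around; they are recorded in every pipeline's provenance log.

## Dual regression: numerical choices

The refinement step solves, per frequency bin, the joint least-squares
system for the three spectral rows given the coefficient maps. Three
post-processing choices were genuinely open and are resolved as follows:

* **Baseline reset.** The raw solution's baseline row is generally not
  flat; it is reset to the constant-1 vector after each refinement, since a
  non-flat thermal baseline would contradict the model's premise. A
  `reset_baseline = FALSE` option exists for sensitivity checks (in our
  experiments it changes the fixed point negligibly).
* **Nonnegativity.** Amplitude spectra are physically nonnegative, so
  negative refined entries (possible under unconstrained OLS) are clipped
  to zero before renormalization.
* **Renormalization every iteration.** Both refined spectra are rescaled
  to unit band sum after every refinement, keeping the coefficient scale
  stable across iterations; without it the coupled scales drift.

Significance of single coefficients uses a two-sided t-test with
$N_b - 3$ degrees of freedom. A one-sided ($\beta > 0$) option is provided
— physiological power contributions are nonnegative by physics — but
two-sided is the default. No multiple-comparison correction is applied
across voxels; the fixed per-voxel threshold is the documented behaviour.
Dominant-frequency ties break toward the lower frequency, and trace
sub-sampling takes the nearest sample at each volume onset with no
anti-alias filtering: aliasing of above-Nyquist physiological harmonics to
$|f - n f_s|$ is part of the modelled physics, not an artifact to remove.

The data-driven initializer needs a *single* spectrum per regressor while
each voxel has its own; the mask-average band spectrum is used, zeroed on
the far side of the split and renormalized — the natural single-spectrum
reading.

## What the generator emulates

`simulate_ground_truth()` + `simulate_epi_dataset()` produce voxel time
series for which the spectral GLM holds *exactly by construction*: band
amplitudes are assembled as $\alpha + \beta_r X_r + \beta_c X_c$ in the
frequency domain, random phases are drawn, and the Hermitian spectrum is
inverse-transformed. This makes recovery tests sharp — with
`noise_scale = 0` the fit reproduces the generating coefficients to
machine precision.

Default conditions mirror a fast-TR 7T protocol: TR 0.328 s (Nyquist
1.524 Hz), 2200 volumes, cardiac rate 1.1 Hz with a slow ±0.05 Hz drift,
respiratory rate 0.3 Hz, three harmonics (the second and third cardiac
harmonics fall above Nyquist and alias into the band), external traces at
1 kHz. Coefficients in modulated voxels are uniform on [0.1, 0.4] — a
regime where physiological peaks clearly exceed the thermal floor, as
observed in fast-TR spectra at high field. `noise_scale` (default 0.3,
relative to the per-bin thermal floor) adds Gaussian per-bin amplitude
perturbations, which keeps the per-bin error model exactly Gaussian and
hence the t-tests exactly calibrated — the package's validation exploits
this for null-calibration checks. A strong component below 0.1 Hz stands
in for neurovascular fluctuations and exercises the `fmin` cut.

What the generator does **not** emulate: motion, distortion and multiband
slice-leakage artifacts; spatially structured physiological maps (voxel
assignments are random, with an `assignment = "co_occurring"` option that
makes cardiac and respiratory modulation coincide in "perfused" voxels);
non-Gaussian, temporally correlated noise; heart-rate variability beyond a
sinusoidal drift. Passing recovery tests on these data therefore
demonstrates correctness of the estimator under its own model, not
robustness to real-scanner artifacts.

Validation problem sizes: recovery and mode-agreement checks use 250–400
voxels × 512 volumes; null calibration uses 2048 voxels × 256 volumes;
oracle comparisons use 100 random instances of ≤ 20 voxels × 32 bins.
These sizes give stable statistics while keeping the full validation run
in seconds.

## Known limitations

* **Mixing invariance of the iteration.** For noiseless data the
  unconstrained dual-regression loop has a family of fixed points: if the
  spectra are replaced by any invertible nonnegative mixture $M X$, the
  spatial step returns maps $A M^{-1}$ and the frequency step returns
  $M X$ again. Only the clip-to-zero and baseline-reset steps break this
  degeneracy, and they cannot remove *positive* admixtures. Consequently
  the data-driven variant converges to spectra that retain part of the
  seed's floor and cross-modal content; its refined cardiac spectrum
  carries somewhat more low-frequency mass than the informed one. The
  *significance masks* of the two modes still agree closely whenever
  cardiac and respiratory modulation co-occur in the same (perfused)
  voxels — the situation in real tissue masks — because mask membership is
  then insensitive to the mixing. With strictly disjoint cardiac-only and
  respiratory-only voxel populations, the data-driven mask over-detects,
  and the informed mode should be preferred.
* **Per-voxel inference ignores spatial structure** (no smoothing, no
  cluster inference) — by design, mirroring the underlying analysis.
* **The respiratory regressor is a proxy.** Belt/pad traces capture chest
  motion, not the diverse mechanisms (susceptibility shifts, CO₂-driven
  flow changes, venous return) that produce respiratory EPI power; the
  dual regression refines the spectrum but inherits the initial labelling.
* **Empty-selection metrics** (`mean_pe()` with no significant voxel)
  return `NA` with `n_selected = 0`, never 0 — downstream group code must
  handle the distinction.

## A compact end-to-end run

```{r example, eval = FALSE}
library(physiodr)
truth <- simulate_ground_truth(n_voxels = 200, n_volumes = 512, seed = 3)
dat <- simulate_epi_dataset(truth)
sp <- band_normalize(amplitude_spectrum(dat$ts), fmin = 0.2)
fit <- dualreg(sp, mode = "data_driven")
summary(fit)
plot(fit)
metrics_report(fit, dat$mask, external = truth$regressors)
```

The README shows this example with the output it prints.
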