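# physiodr

Frequency-domain physiological modelling of fast-TR resting-state fMRI by
iterative dual regression.

## The problem

When echo planar imaging (EPI) is acquired fast enough (TR of a few hundred
milliseconds), the cardiac frequency regime is resolved rather than aliased
into the low-frequency band, and cardiac- and respiratory-cycle signal
fluctuations become measurable per voxel. Changes in cerebral cardiac
pulsatility have been linked to arterial stiffening in aging and small
vessel disease, so these "noise" components are a signal of interest in
their own right. `physiodr` is for researchers who want to map and quantify
those physiological contributions from fast-TR EPI — with or without
external physiological recordings.

## The model

Let `S(t_1…t_N)` be a voxel's time series at repetition time TR. Its
one-sided amplitude spectrum `P(f)` (magnitude of the Fourier transform) is
restricted to the band `[f_min, 1/(2·TR)]` (default `f_min` = 0.2 Hz, above
the neurovascular regime) and normalized to unit band sum. Each voxel's
normalized spectrum is modelled as a general linear model

    P(f) = α·1 + β_r·X_r(f) + β_c·X_c(f) + ε(f)

with a constant thermal-noise baseline `1`, a respiratory spectrum `X_r`
and a cardiac spectrum `X_c`, each also unit-sum normalized. The
normalization couples the coefficients: for a noiseless voxel,
`α·N_b + β_r + β_c = 1` over `N_b` band bins.

The regressor spectra are refined by **iterative dual regression**:

1. *Spatial GLM*: fit `(α, β_r, β_c)` per voxel over frequencies.
2. *Frequency GLM*: holding the coefficient maps fixed, solve per frequency
   bin for refined spectral rows; reset the baseline row to 1, clip
   negative entries, renormalize.
3. Iterate until the L1 change of both refined spectra drops below 0.01.

The initial guess comes either from externally recorded pulse-oximetry and
respiratory-belt traces sub-sampled to the TR (**informed** mode — above-
Nyquist harmonics alias exactly as in the EPI data, at `|f − n·f_s|`), or
from the EPI spectra themselves split at 0.6 Hz (**data-driven** mode).

Fitted maps are summarized by partial-volume-weighted means over
significant voxels, `⟨β⟩ = Σ β·PVE / Σ PVE` (PVE > 0.7, p < 0.01), the
spatial extent `R = Σ_sig PVE / Σ_mask PVE`, and a windowed cardiac
pulsatility metric (mean band power in a 0.04 Hz window at the dominant
external cardiac frequency).

## Worked example

```r
library(physiodr)

truth <- simulate_ground_truth(n_voxels = 200, n_volumes = 512, seed = 3)
dat   <- simulate_epi_dataset(truth)

sp  <- band_normalize(amplitude_spectrum(dat$ts), fmin = 0.2)
fit <- dualreg(sp, mode = "data_driven")
summary(fit)
#> Iterative dual regression of EPI band spectra
#>   200 voxels, 223 band bins in [0.2, 1.524] Hz, init: data_driven
#>   converged after 5 iteration(s) (tolerance 0.01; final L1 change: cardiac 0.0041, respiratory 0.00668)
#>   dominant frequencies: cardiac 1.06 Hz, respiratory 0.2918 Hz
#>   significant at p < 0.01: cardiac 97/200, respiratory 112/200 voxels
#>   mean PEs: alpha 0.00288, beta_r 0.181, beta_c 0.177

metrics_report(fit, dat$mask, external = truth$regressors)
#> Physiological-modulation metrics (grey matter, PVE > 0.7, p < 0.01)
#>   mean PEs  <alpha> 0.003192  <beta_r> 0.3411  <beta_c> 0.3787
#>   spatial extent  Rc 0.349  Rr 0.501  (25 / 36 / 73 cardiac / respiratory / mask voxels)
#>   cardiac pulsatility metric (0.04 Hz window): all voxels 0.005427, significant only 0.008091

cor(coef(fit)[, "beta_c"], truth$beta_c)
#> [1] 0.9901948
```

The 512-volume scan at TR 0.328 s gives a 1.524 Hz Nyquist frequency, so
the analysis band holds 223 bins. The data-driven fit converges in five
iterations; its dominant cardiac frequency (1.06 Hz) sits within a bin of
the generating 1.1 Hz rate, and the recovered cardiac coefficient map
correlates 0.99 with the ground truth. `Rc = 0.349` means ~35% of the
PVE-weighted tissue mask shows significant cardiac modulation.

The fit object supports `print`, `summary`, `coef`, `fitted`, `residuals`,
`predict` and `plot`. `run_pipeline()` runs the whole chain from NIfTI
files on disk, and `inst/cli/physiodr.R` wraps `simulate` and `pipeline`
as shell commands.

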