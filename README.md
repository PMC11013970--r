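# dmdstack

Dynamic mode decomposition (DMD) and its delay-embedded higher-order
variant (HoDMD) for fluorescence-microscopy image stacks: reconstruction,
denoising, mode analysis, and prediction of unseen frames along the stack
axis. The stack axis can be time (time-lapse series), z (3-D stacks along
the optical axis), or the polarization angle of a rotating linearly
polarized excitation laser (two-photon polarimetry sweeps).

The package is aimed at microscopists working with photon-starved data —
multiphoton imaging of dim intrinsically fluorescent probes, 3-D STED
stacks, polarimetry sweeps with superimposed photobleaching — who want a
linear, interpretable alternative to black-box denoisers, plus a synthetic
phantom/PSF/noise simulator so every claim is testable without microscope
data.

## The method

Each frame of an `(x, y, m)` stack is flattened into a column of the
snapshot matrix `X = [x_1 ... x_m]` (n = x·y pixels). DMD approximates the
one-step propagator `A` in `x_{k+1} = A x_k` — a finite-dimensional
approximation of the Koopman operator of the underlying dynamics — from
the shifted pair `X_1 = [x_1 ... x_{m-1}]`, `X_2 = [x_2 ... x_m]` via a
truncated SVD `X_1 = U Σ V*` and the reduced r×r operator

    Ã = U* X_2 V Σ⁻¹ .

Its eigendecomposition gives discrete eigenvalues `λ_j`, exact DMD modes
`φ_j = X_2 V Σ⁻¹ w_j`, amplitudes `b_j` (fitted by least squares over all
snapshots — the noise-robust "optimal DMD" amplitude fit), and the
expansion

    x_k = Σ_j φ_j λ_j^{k-1} b_j ,      ω_j = log(λ_j) / Δ ,

so `x(c) = Σ_j φ_j e^{ω_j c} b_j` evaluates the model at *fractional*
frame coordinates: interpolation of frames that were never acquired.
`Re(ω)` is decay (photobleaching gives a single real `λ` slightly below
1), `Im(ω)` is oscillation (orientation response in polarimetry,
non-monotonic axial profiles in z-stacks). Rank truncation uses the
optimal singular-value hard threshold for the matrix aspect ratio (noise
level estimated from the median singular value), which separates signal
modes from the shot-noise plateau automatically.

When the spectral complexity of the data exceeds its spatial rank —
the standing wave `sin(x)·cos(ωk)` is the canonical case, and mode mixing
in z-stacks is its microscopy symptom — plain DMD cannot produce the
required conjugate eigenvalue pairs. HoDMD (DMD-d) fixes this by
delay-embedding `d` shifted copies of the spatially reduced snapshots
before the decomposition, then lifting the modes back to pixel space.

## Worked example

Denoise a low-photon bleaching series (the generator reproduces the
regime of multiphoton imaging of a dim sterol probe: ~20 photons peak
signal, 2% intensity loss per frame, Poisson noise):

```r
library(dmdstack)
ser   <- make_series(series_spec("bleach", seed = 1))   # truth + Poisson observation
model <- fit_dmd(ser$observed)                          # automatic hard-threshold rank
print(model)
#> <dmd_model> rank 1, delay 1, 50 frames along time axis
#>   |lambda| in [0.9804, 0.9804], 0 oscillatory eigenvalue(s)
```

A single real mode suffices, and its eigenvalue is the bleaching factor:
`λ = 0.9804` against the generative `e^{-0.02} = 0.9802`, i.e. a decay
rate `ω = -0.0198` per frame. The rank-1 reconstruction is dramatically
cleaner than the input:

```r
recon <- reconstruct(model)
quality_report(ser$truth, recon)
#> <quality_report> 50 frames
#>   PSNR [33.85, 42.32] dB, SSIM [0.9681, 0.9761], mean MSE 0.07273
```

versus a mean PSNR of 20.8 dB for the raw noisy input — an ~17 dB
denoising gain on every frame.

Other entry points: `fit_hodmd()` (delay embedding), `downsample()` /
`predict_frames()` / `linear_interpolate()` (axial up-sampling and its
baseline), `analyze_polarimetry()` (peak angles + mode classification),
`make_phantom()` / `make_psf()` / `convolve_stack()` / `add_poisson()`
(synthetic ground truth), `psnr()` / `mse_ssim()` / `singular_spectrum()`
(quality metrics). A command-line tool wrapping all workflows is installed
at `inst/scripts/dmdstack` with subcommands `denoise`, `interpolate`,
`polarimetry`, `phantom`, `eval`.

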