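---
title: "Dynamic mode decomposition of microscopy image stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic mode decomposition of microscopy image stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmdstack)
```

## The model

An image stack is a data cube with image coordinates x and y and a third
axis whose meaning is declared, not inferred: time for time-lapse series,
z for 3-D stacks, or the polarization angle θ for two-photon polarimetry
sweeps. Flattening each frame into a column gives the snapshot matrix
`X ∈ R^{n×m}` with `n = x·y`. DMD postulates a linear one-step propagator,

$$x_{k+1} = A\,x_k,$$

the finite-dimensional surrogate of the Koopman operator of the (generally
nonlinear) imaging dynamics, and estimates it from the shifted snapshot
pair `X₁` (frames 1…m−1) and `X₂` (frames 2…m) as the Frobenius-norm
minimizer `A = X₂ X₁⁺`. `A` (n×n) is never formed: with the truncated SVD
`X₁ ≈ U Σ Vᵀ` of rank r, the reduced operator

$$\tilde A = U^{\mathsf T} X_2 V \Sigma^{-1} \in \mathbb{R}^{r\times r}$$

is similar to the restriction of `A` to the retained subspace.
Eigenpairs `(λ_j, w_j)` of `Ã` yield *exact* DMD modes
`φ_j = X₂ V Σ⁻¹ w_j` (normalized to unit Euclidean norm), and the data are
expanded as

$$x_k = \sum_{j=1}^{r} \varphi_j\, \lambda_j^{\,k-1}\, b_j,
\qquad \omega_j = \log(\lambda_j)/\Delta,$$

with `Δ` the frame spacing. `|λ| < 1` is decay (photobleaching appears as
a single real eigenvalue slightly below unity), `arg λ ≠ 0` is
oscillation. The continuous form `x(c) = Σ φ_j e^{ω_j(c - c_0)} b_j`
evaluates the model between acquired frames, which is what axial
up-sampling uses.

We chose exact modes over projected modes (`U w_j`) because they remain
well behaved when the model is evaluated outside the span of `X₁`, which
interpolation does routinely. The two coincide on consistent data.

### Amplitudes

Amplitudes are fitted by least squares over *all* snapshots
(`method = "all_frames"`, the default): minimize
`Σ_k ‖Φ diag(λ^{k-1}) b − x_k‖²`, solved through the Gram/Vandermonde
normal equations `[(Φ^HΦ) ∘ (W̄ Wᵀ)] b = diag-sum(W̄ ∘ Φ^H X)` with
`W_{jk} = λ_j^{k-1}`. This is the amplitude-optimal ("optimal DMD") fit:
on noiseless consistent data it agrees with fitting the first frame only,
and on noisy data its reconstruction residual can only be smaller, which
our tests assert directly. Full variable projection of the eigenvalues
themselves is deliberately out of scope — at the problem sizes targeted
here the amplitude-linear fit is the part that matters for noise
robustness — and is an extension point. Rank-deficient mode matrices fall
back to the minimum-norm (pseudoinverse) solution with a warning.

### Rank selection

Three policies are exposed (`rank_policy()`):

* `hard_threshold` (default): the optimal singular-value hard threshold
  for the matrix aspect ratio β = min(dim)/max(dim), with unknown noise
  level estimated from the median singular value. The coefficient
  `ω(β) = λ*(β)/√μ_β` is computed exactly — `μ_β` is the median of the
  Marchenko–Pastur distribution, obtained by numerical integration and
  root finding — rather than from the published lookup table. Shot-noise
  plateaus in the singular spectrum fall below this threshold, which is
  why a Poisson-corrupted bleaching series keeps exactly one mode.
* `fixed`: `min(fixed_rank, available)` components.
* `energy`: smallest rank reaching a cumulative squared-singular-value
  fraction. `energy_fraction = 1` retains the full numerical rank, the
  right choice for noiseless control experiments where the hard
  threshold's noise model does not apply.

Every policy retains at least one component and never retains singular
values at round-off level (`max(dim)·ε·σ₁`), since inverting those is
meaningless; the degenerate all-zero matrix is an error ("no signal").

### Delay embedding (HoDMD)

Plain DMD is limited by the *spatial* rank of the snapshot matrix: a
standing wave `sin(x)cos(ωk)` has a rank-1 snapshot matrix but needs the
conjugate pair `e^{±iω}` — plain DMD cannot deliver it, and the microscopy
symptom of the same deficiency is mode mixing, where structure confined to
the central frames of a z-stack smears across the whole reconstruction.
`fit_hodmd()` implements DMD-d: (1) a first truncated SVD reduces the
snapshots spatially to dimension r₁; (2) d time-shifted copies of the
reduced snapshots are stacked into an `(r₁·d) × (m−d+1)` augmented matrix;
(3) standard DMD runs on the augmented matrix; (4) modes are lifted back
through the first-stage basis, taking the leading delay block of each
augmented eigenvector (the remaining blocks differ only by unit-modulus
factors that the amplitudes absorb); (5) amplitudes are fitted against the
original, non-augmented snapshots. Reducing spatially *before* embedding
keeps memory flat in d with no accuracy cost. With `d = 1` the pipeline
reduces to plain DMD, which a test asserts to 1e-8.

The same rank policy is applied to both SVD stages; nothing in our
experiments favoured decoupling them. The number of recoverable
eigenvalues is bounded by both `r₁·d` and `m−d`, so the gain is over the
spatial-rank limit, not over the snapshot count itself. Useful delays in
practice: `d ≈ 10` for z-stacks, `6` for polarimetry sweeps, `4` for
smooth STED-like stacks; `d·r₁` exceeding the `m−d+1` augmented snapshots
triggers an overfitting warning. Automatic selection of d is a non-goal;
the delay is a statement about expected spectral complexity that the user
makes.

## Workflows

**Denoising/reconstruction.** `reconstruct()` evaluates the discrete
expansion at integer frame indices and returns the real part; the largest
discarded imaginary magnitude is attached as a diagnostic
(`imag_residual`), at round-off level whenever the spectrum is
conjugate-closed. Reconstructions may undershoot zero (ringing); values
are kept as-is, with clipping left to display export.

**Axial up-sampling.** `downsample()` keeps frames `1, 1+s, …` (40 frames
at stride 3 keep 14) and records the removed indices; a model fitted to
the coarse stack (step `s·Δ`) is evaluated by `predict_frames()` at the
removed coordinates — fractional powers of λ on the coarse grid.
Extrapolation beyond the acquired range is refused by default: Koopman
linearity is an in-window assumption. The pixel-wise
`linear_interpolate()` baseline and `evaluate_interpolation()` (per-frame
MSE/SSIM for both methods) complete the comparison. Because DMD denoises,
it can score *higher* MSE than linear interpolation on a noisy reference
while looking cleaner; SSIM is the more faithful score there.

**Polarimetry.** `analyze_polarimetry()` fits HoDMD (default `d = 6`),
reconstructs, and reads the intensity peaks off the *reconstructed*
integrated-intensity profile with circular wrap-around and no sub-bin
refinement — peaks are reported at the sampled-angle precision, matching
how such sweeps are read in practice. `classify_modes()` bins eigenvalues
by `|Im λ|/|λ| > imag_tol` (oscillatory; conjugate pairs count as two) and
by modulus against `1 ± unit_tol` (decaying/constant). The defaults
`imag_tol = unit_tol = 1e-3` separate Poisson jitter from genuine
oscillation at the photon budgets the generator emulates. A cos 2θ
orientation response gives two peaks 180° apart plus a real eigenvalue
just below unity for bleaching — the component a plain Fourier analysis
cannot absorb. `dft_compare()` demonstrates the complementary fact: after
per-pixel mean subtraction DMD *is* the temporal DFT, with all eigenvalues
on the unit circle at roots of unity (asserted to 1e-6 on periodic and on
random stacks).

## The synthetic generator

`make_series()`, `make_phantom()`, `make_psf()`, `convolve_stack()` and
`add_poisson()` provide ground truth for every test. The reference
conditions, chosen once:

* **bleach**: 32×32 pattern of smooth blobs, 50 frames, decay 0.02/frame,
  peak ≈ 20 photons at `photon_scale = 1` — the low-photon multiphoton
  regime where denoising is actually needed.
* **polarimetry**: 36 angles at 10° steps, θ₀ = 100°, modulation depth
  0.8, bleaching 0.005/frame (≈ 17% loss over the sweep), static
  background 2.
* **standing_wave**: 8×8 × 30 frames, ω = 0.3 rad/frame, background 0.
  The pure product is a rank-1 matrix; an optional background raises the
  rank to 2. It takes negative values and is used noise-free — it is a
  mathematical control, not an imaging condition.
* **axial_envelope**: 40 frames, Gaussian axial weight of σ = 4 frames
  centred mid-stack — structure confined to central frames, the
  mode-mixing test case.
* **phantom**: filled/shell spheres on a constant background;
  `random_phantom_spec()` defaults to 5 spheres of radii 8–20 voxels in
  128×128×100 (tests use smaller volumes). With background 0, frames
  beyond the sphere extent are exactly empty (matrix rank 0) — the sharp
  transitions that defeat low-rank reconstruction until PSF convolution
  redistributes intensity to neighbouring planes.
* **PSF**: scalar-diffraction defocus integral (Born–Wolf-type), defaults
  NA 1.4, emission 520 nm, n 1.515, sampling 25 nm xy / 50 nm z,
  normalized to unit total intensity; computed by quadrature over the
  pupil radius. No vectorial/high-NA corrections and no STED depletion
  simulation — the PSF's role here is realistic band-limiting, not optics
  research.
* **noise**: each voxel is `Poisson(photon_scale · value)/photon_scale`;
  `photon_scale` converts intensity into expected photons and hence sets
  the SNR. Zero intensity stays exactly zero; seeds make draws
  bit-reproducible without disturbing the caller's RNG state.

What the generator does *not* emulate: detector read noise and gain,
sample drift, depth-dependent aberrations, spatially varying background,
or pixel-wise orientation disorder in polarimetry (a single global θ₀ is
used). Passing tests therefore demonstrate correctness of the
decomposition machinery and its qualitative behaviours — not performance
claims on any particular instrument's data.

## Numerical choices

* All internal math is double precision; TIFF output is 32-bit float,
  written as-is (no rescaling or clipping, negatives survive).
* Flattening order is R's native column-major `as.vector` order,
  single-sourced in `to_snapshot_matrix()`/`from_snapshot_matrix()`. Any
  fixed bijection is equivalent — the decomposition is invariant under
  pixel permutation — but modes only reshape correctly if the convention
  has exactly one home.
* Frame k maps to coordinate `origin + (k−1)·step`; exponents use `k−1`.
* `ω = log(λ)/Δ` uses the principal branch; frequencies near Nyquist
  (`arg λ ≈ ±π`) are inherently sign-ambiguous and are reported on the
  principal branch, not unwrapped. `λ = 0` modes have no continuous form;
  they are flagged and skipped in fractional-coordinate evaluation.
* Mode ordering is deterministic: descending `|b_j|·|λ_j|^{(m−1)/2}`
  (an energy proxy across the acquisition window), ties broken by
  descending `|λ|`, then ascending `arg λ` — so CSV exports are
  reproducible.
* Eigendecomposition of a real reduced operator yields exactly
  conjugate-paired spectra (LAPACK), which the conjugate-closure property
  test confirms end to end.
* SSIM uses the standard Gaussian-window formulation (σ = 1.5, 11×11,
  K1 = 0.01, K2 = 0.03, data range of the reference, valid-window
  averaging); it was verified against an independent per-window evaluation
  of the formula and agrees with scikit-image to 1e-7 on shared fixtures.
  Note that SSIM of an image against its negative is only negative when
  *local* window means vanish; with nonzero local means both the luminance
  and covariance terms change sign.
* 3-D convolution is an FFT product on zero-padded 5-smooth sizes, cropped
  "same" with the kernel centre aligned; boundary structures within half a
  kernel of the edge lose intensity accordingly.
* PSNR needs a reference: on synthetic data that is the known truth. For
  real data without ground truth any PSNR figure inherits its reference's
  meaning, and the package does not pretend otherwise.

## Problem sizes

The tests and the acceptance script run on 32×32 to 64×64 frames with
30–50 frames per stack and 40×40×30 phantom volumes — sizes at which every
workflow completes in seconds while exercising identical code paths to
full-resolution data; nothing in the implementation is specific to these
sizes.

## Known limitations

* No streaming, compressed, randomized or multi-resolution DMD variants;
  no eigenvalue-refining variable projection.
* No automatic delay selection; no proprietary microscope file formats
  (single-channel TIFF only); multi-channel files must be split upstream.
* Peak finding reports sampled-angle precision only; dipole-orientation
  physics (order parameters, cone angles) is out of scope.
* Extrapolation beyond the acquired window is possible only by explicit
  override, and its quality is whatever the linear model deserves there.
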