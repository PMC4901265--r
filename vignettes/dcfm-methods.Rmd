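---
title: "Digital color fusion microscopy: models, parameters, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital color fusion microscopy: models, parameters, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the numerical
choices that affect results, and what the synthetic test bed does and does
not establish about real data.

# The imaging model

A lens-free on-chip microscope records in-line holograms: the intensity of
the interference between light scattered by the sample and the unscattered
reference beam, on a sensor a few hundred micrometres below the sample,
with no lenses. The field of view equals the sensor's active area (tens of
mm²) and the resolution is set by the pixel pitch and the reconstruction,
not by an objective — but a single-wavelength acquisition carries no color.
A lens-based microscope (benchtop or phone-camera based) supplies color at
low resolution. The package's premise, inherited from the fusion
literature, is that in most specimens — H&E-stained tissue prominently —
chroma varies more slowly than brightness, so an image whose fine detail is
monochrome but whose coarse structure is accurately colored is
perceptually and diagnostically adequate.

# Holographic reconstruction

## Angular-spectrum propagation

`angular_spectrum_propagate()` decomposes the field into plane waves with a
2D FFT, multiplies each by `exp(i 2π dz sqrt((n/λ)² − fx² − fy²))`, and
inverts. Conventions that matter:

* Frequency grid `fx ∈ [−1/(2 pitch), 1/(2 pitch))`, the standard FFT
  layout; units are cycles/µm, z in µm, wavelengths in nm.
* Evanescent components (`fx² + fy² > (n/λ)²`) are hard-zeroed. This makes
  propagation unitary on the propagating band (energy conserved to 1e−8 in
  the tests) and composable: `P(dz1)∘P(dz2) = P(dz1+dz2)`.
* Odd-sized inputs are padded to even size by edge replication and cropped
  after. No further padding is applied: the z distances here (≤ a few
  hundred µm at 0.5 µm pitch) keep diffraction spreading well inside the
  frame for the field sizes used.

## Autofocus

The sample-to-sensor distance is estimated by back-propagating
`sqrt(intensity)` over a coarse grid (21 steps by default) and maximizing
the Tamura coefficient (`sqrt(sd/mean)`) of the gradient magnitude of the
amplitude, then refining with `stats::optimize` between the coarse
neighbors. The criterion function is an argument, so other sharpness
metrics can be plugged in. Sharpness autofocus needs edge content: it
resolves the focus of phantoms with sharp absorbing structures to a few µm,
but is weakly conditioned on very smooth objects — which is physics, not
implementation.

## Transport-of-intensity initialization

The axial derivative `∂I/∂z` is taken as the finite difference of the first
and last stack planes (the pairing is configurable; first/last maximizes
the lever arm). Assuming slowly varying intensity, the phase solves a
Poisson equation, inverted in the Fourier domain with the denominator
`max(k⊥², ε·k⊥,max²)`. The default `ε = 1e−3` deliberately suppresses the
lowest spatial frequencies, where the finite-difference approximation and
sensor drift dominate on real data; with noiseless synthetic data and
`ε = 1e−5` the inversion is essentially exact (correlation > 0.999 with the
true phase in the tests). The output is zero-mean — the global phase is
unobservable.

## Multi-height phase recovery

Planes are sorted by ascending z (enforced). The iterate starts at the
first plane as `sqrt(I₁)·exp(i φ_TIE)` and sweeps forward and backward; at
each plane the amplitude is averaged with the measured `sqrt(I)`, the phase
kept. Convergence is monitored as the RMS change of the first-plane
amplitude between sweeps; the loop stops below `1e−4` or after 20 sweeps,
consistent with the 10–20 sweeps this family of algorithms typically
needs. The converged field is back-propagated to the object plane from the
first (closest) plane by default; `final_plane` selects another. On
noiseless 8-height synthetic stacks, reconstruction-truth amplitude
correlation exceeds 0.99 and the first-plane data misfit never increases
between sweeps.

## Tilt correction

Per-region autofocus distances are fitted with a least-squares plane
(`fit_tilt_plane()`); the slopes give the object's tilt angles. During
recovery the amplitude constraint is applied on the sensor-parallel plane:
the iterate is rotated with a rotational transformation of its angular
spectrum, updated, and rotated back. Numerical design of
`rotate_field()`:

* The spectral remap interpolates `F(fx·cosθ + fz·sinθ)` with natural cubic
  splines and includes the Jacobian `|cosθ − (fx/fz)·sinθ|`.
* The content's circular energy centroid is shifted to the coordinate
  origin before the remap. Without this the spectrum carries a linear phase
  at the Nyquist rate (π per frequency bin for centered content), which no
  interpolation can follow. The rotation axis thus passes through the
  content.
* The field is zero-padded twofold so the spectrum is oversampled relative
  to its variation scale.
* A dominant uniform background — the unscattered reference wave — is split
  off whenever `|mean| > rms deviation` and rotated analytically as a
  tilted plane wave (transverse frequency `sin θ·n/λ`, Jacobian `1/cos θ`):
  a rotated constant is an off-grid spectral delta that interpolation would
  smear across the band. Because any finite frame is periodic while the
  tilted carrier is not, the unavoidable wrap seam is placed at the
  antipode of the content centroid.
* Inside the recovery loop only the *update correction* is rotated back,
  not the full field, so interpolation error scales with the (shrinking)
  update. The initial TIE-phase guess is used unrotated — rotating a field
  whose phase is not yet physical only injects noise.

With zero tilt the code path is identical to the plain algorithm (the
reduction is exact, asserted bitwise). The benefit of the correction grows
with the lateral extent of the field, since the tilt-induced defocus spread
is `x·tanθ`: on a 128 µm-wide synthetic field tilted by 1.5° the corrected
reconstruction correlates with the truth visibly better than the
uncorrected one, while on small crops the defocus spread is below the depth
of field and the correction cannot help. The test suite therefore exercises
tilt on the full 256² phantom.

# Colorimetry and calibration

## Standard-observer machinery

The CIE 1931 2° color matching functions and the D65 spectral power
distribution are shipped as package constants on the 400–700 nm, 10 nm
grid (31 samples) used by the hyperspectral ground-truth procedure.
Normalization makes a perfect transmitter integrate to Y = 1, so Lab
lightness is anchored to the illuminant white; the same white point is the
default for all Lab conversions. RGB means linear sRGB primaries under D65
(the fixed IEC matrices); out-of-gamut values pass through unclipped so
conversions round-trip exactly, and are flagged. CIE-94 uses the
graphic-arts constants (kL = kC = kH = 1, K1 = 0.045, K2 = 0.015) with the
first argument as the reference color; the formula's reference-color
asymmetry is inherent and not hidden.

## The four calibration steps

1. **White balance** divides by an empty-field capture (per-pixel for
   images, per-channel scalars for patch sets), with a floor of 1e−4 of the
   empty image's median to avoid division blow-ups at dead pixels.
2. **Lightness** is corrected by a least-squares polynomial, degree 1 by
   default — appropriate when the camera response is linear, which raw
   (gamma-free) captures are.
3. **Chroma** is rescaled by one global scalar `s = Σc_o·c_t / Σc_o²`,
   applied jointly to a and b so hue angles are preserved. One scalar (not
   per-hue) matches a desaturation-type distortion.
4. **Color transform**: the 3×10 matrix over the full second-order
   monomials of (L, a, b), constant term included, solved by pseudoinverse;
   the term ordering is versioned in serialized models. If the feature Gram
   matrix's condition number exceeds 1e12 a ridge-regularized solve is used
   and a warning raised.

Steps 3 and 4 are least-squares fits nested inside richer families, so on
the training patches the mean ΔE₉₄ is non-increasing across steps; step 2
minimizes lightness SSE rather than ΔE₉₄ directly, so its monotonicity is
generic but not a theorem — the test fixes the seed. Patch sets need
m ≥ 10 (the transform has 10 columns); the fabricated-checker layout used
throughout is 46 patches (22 + 24). The package trains and evaluates on
the same 46 patches, as the underlying procedure does; `fit_calibration()`
returns per-step training diagnostics so overfit can be inspected.

# Preprocessing and registration

Channel alignment, pair registration and the synthetic misalignments all
share one projective-registration engine: a grid of control points (6×6 by
default) matched by phase correlation — Hann-windowed, zero-mean,
spectrally whitened with exponent 0.75 rather than 1, which keeps the
correlation peak sharp without amplifying noise-dominated frequencies when
one image is strongly blurred — with parabolic subpixel refinement; then a
normalized DLT homography inside RANSAC (1 px inlier threshold, 400
deterministic minimal samples drawn from an internal
linear-congruential generator so the global RNG stream is untouched). A
second estimate-warp-refine pass removes the bias local translation
matching incurs under rotation or perspective within a patch. Transforms
indistinguishable from the identity (corner displacement < 0.1 px) skip the
resampling, making channel alignment exactly idempotent. Denoising is
multi-level hard thresholding at the universal threshold
`σ̂·sqrt(2 ln M)`, with `σ̂` the MAD/0.6745 of the finest diagonal band;
the approximation band is never touched, so the image mean is preserved.

# Wavelet fusion

The 2D multilevel DWT uses the biorthogonal 3.7 filter bank (the standard
B-spline constants, frozen in source). The image is padded symmetrically to
a multiple of 2^N once at the top; internally the filter bank is applied
with periodized convolution (filters folded modulo the band length), which
gives perfect reconstruction to machine precision at every level — the
identity tests assert ~1e−13. Because coefficients differ across boundary
conventions, this choice is fixed and documented.

Fusion proper: per channel, the grayscale reconstruction is
contrast-matched to the channel by quantile-mapping histogram matching
(exact identity when source equals reference; a constant reference yields a
constant output), both are decomposed to N levels, and the fused pyramid
takes the approximation from the color channel and all detail bands from
the matched grayscale image. `choose_levels()` maps the effective-pixel
ratio to `N = clamp(ceil(log2 ratio) + 4, 4, 6)` — the formula is an
engineering fit reproducing the depths used in practice (ratio ≈ 3.1 → 6,
≈ 1.24 → 5, 1 → 4); the user can always override. At N = 6 with weak
lens-based modulation a warning flags the known color-fluctuation artifact
of deep decompositions.

Two properties bound what fusion can do. First, the fused level-N
approximation equals the color channel's by construction, so color errors
in the lens-based arm below that band pass straight through. Second, the
detail bands come from a *single* grayscale image mapped through one global
monotone function per channel: where the true image's channels diverge at
fine scales — sharp hue edges — the fused detail is systematically
imperfect. The brightness-vs-chroma assumption above is exactly the regime
where this error is small; the test suite measures a > 5 dB PSNR gain over
the blurred arm on a smooth-chroma phantom, and a smaller (but still
positive, in both PSNR and pixelwise ΔE₉₄) gain on the two-tone tissue
phantom whose class boundaries are hue edges.

# The synthetic test bed

`make_tissue_phantom()` emulates an H&E field: low-frequency pink "stroma"
texture, Poisson-placed elliptical purplish-blue "nuclei" with sharp
boundaries, per-pixel ground-truth RGB, and a complex object whose
amplitude follows luminance (absorbing stain) with a proportional phase.
`simulate_hologram_stack()` runs the angular-spectrum forward model at each
height, optionally through a tilted plane, with Gaussian shot-like noise
(sd ∝ sqrt(intensity)) — a Gaussian approximation chosen in the absence of
a sensor model. `make_checker_spectra()` draws 46 smooth band-pass
transmission curves (2–4 Gaussians, clipped to [0,1], 22 + 24 split);
these are synthetic stand-ins for theatrical filter sets, so tests assert
structure (count, [0,1] range, chromaticity-hull coverage > 0.05), never
specific filter identities. `render_camera()` integrates spectra against
per-channel responsivities (colorimetric CMF-derived curves by default,
optionally wavelength-shifted per channel), applies channel gains,
desaturates in Lab by a configurable factor, and adds seeded noise — the
default distorted camera (desaturation 0.5, shifts (+12, −10, +8) nm,
gains (1.3, 1.0, 0.8), noise 0.005) emulates the gray-aggregated
chromaticity clouds raw phone captures show. `degrade_to_lensbased()`
models the resolution gap (blur, down/up-sampling) plus projective
misalignment and per-channel offsets. All generators are deterministic
under a seed, recorded in their outputs.

What passing tests do *not* show: real sensors have structured (Bayer,
fixed-pattern) noise, partially coherent illumination blurs holograms
beyond the ideal forward model, real filter spectra are not Gaussian
mixtures, and real lens aberrations are not projective. The synthetic
results validate the algorithms' correctness and their relative ordering
(calibrated beats uncalibrated, fused beats blurred, tilt-corrected beats
uncorrected), not instrument-grade absolute numbers.

# Problem sizes and runtime choices

The shipped tests run phantoms at 128–256², hologram stacks of 3–8 heights,
and one 512² 8-height convergence check; these sizes keep the full suite in
the low minutes on one core while leaving every algorithmic branch
exercised. The end-to-end driver defaults (`dcfm_config()`): 256² phantom,
8 heights from 300 µm in 15 µm steps (the hyperspectral ground-truth
acquisition used 10 heights at 15 µm; 8 keeps the runtime proportionate
while remaining inside the regime where recovery converges), λ = 532 nm,
0.5 µm pitch, blur σ = 3 px with 4× down/up-sampling for the lens-based
arm, desaturation 0.5 and gains (1.3, 1.0, 0.8) for the camera, fusion at
N = 4.

# Known limitations

* Chroma resolution is bounded by the lens-based arm — by design.
* Pixel super-resolution is out of scope; any upsampled hologram stack can
  be supplied, and `match_pixel_size()` is the hook where a super-resolved
  grid would enter.
* The rotational transform's accuracy degrades with angle and with
  spectrum sharpness; beyond a few degrees the analytic-carrier seam and
  interpolation error become visible. Tilts in the intended range (≲ 2°,
  the plane-fit regime) are safe.
* `fit_color_transform()` extrapolates second-order polynomials; colors far
  outside the checker gamut may be mapped poorly. More patches, a LUT or a
  network calibration are the standard remedies.
* Registration assumes overlapping content with shared features; it fails
  loudly (match counts in the error) rather than silently.
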