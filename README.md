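# dcfm — Digital Color Fusion Microscopy

Lens-free on-chip holography images centimetre-scale fields of view at
sub-micron resolution, but at a single wavelength: its reconstructions are
grayscale. Conventional lens-based color microscopes render color well, but
a low-magnification objective (or a phone camera) trades resolution for
field of view. `dcfm` implements the computational bridge between the two:
it reconstructs a high-resolution grayscale image from a stack of in-line
holograms, color-calibrates the low-resolution lens-based image, and merges
the pair in the wavelet domain so that fine structure comes from holography
and color comes from the calibrated camera. The intended users are
computational-microscopy and digital-pathology researchers who want
color-accurate, high-resolution imagery from inexpensive hardware.

## The three algorithmic cores

**Holographic reconstruction.** An in-line hologram records only intensity,
so the lost phase is retrieved from measurements at several sample-to-sensor
distances z. A field U is moved between planes with the angular-spectrum
operator

    U(z + dz) = F^{-1}[ F[U(z)] · exp( i 2π dz √((n/λ)² − f_x² − f_y²) ) ]

(evanescent components hard-zeroed). Recovery starts from a
transport-of-intensity (TIE) phase estimate, solved by a regularized
Fourier-domain Poisson inversion of the axial intensity derivative, then
sweeps the z-stack forward and backward: at each plane the amplitude is
replaced by the average of the current guess and √(measured intensity), the
phase is kept. A tilted sample is handled by a rotational transformation of
the angular spectrum onto the sensor-parallel plane before each amplitude
update; the tilt angles come from least-squares plane fitting of per-region
autofocus distances (Tamura sharpness criterion).

**Four-step color calibration.** Fitted once per imaging system on a
46-patch transmission color checker whose ground truth comes from
hyperspectral imaging through the CIE 1931 standard observer under D65:
(1) white-balance by an empty-field capture; (2) least-squares polynomial
(default linear) correction of CIELAB lightness; (3) one least-squares
chroma scale s = Σc_obs·c_truth / Σc_obs² undoing desaturation; (4) a 3×10
matrix **U** mapping the full second-order monomials (1, L, a, b, L², a²,
b², La, Lb, ab) onto ground-truth Lab, solved by pseudoinverse. Color error
is quantified throughout with the CIE-94 distance ΔE₉₄.

**Wavelet fusion.** After pixel-size matching, projective registration of
the lens-based image onto the lens-free grid, and per-channel histogram
matching of the grayscale reconstruction, both images are decomposed with
the biorthogonal 3.7 wavelet to N levels (N = 4–6, deeper for a larger
resolution gap). The fused pyramid takes the level-N approximation from the
color channel and every detail band from the holographic image; inverse
transforms of the three channels form the output RGB image.

A seeded synthetic module (tissue-mimicking phantoms, forward-simulated
hologram stacks, synthetic checker spectra, distorted-camera renderings,
degraded lens-based views) makes the entire pipeline testable without
instrument data.

## Worked example

```r
library(dcfm)
res <- run_dcfm(dcfm_config(seed = 3, size = 256))
res$report
#>       image pixelwise_mean_de94 region_mean_de94
#> 1     fused            2.924673        0.7202861
#> 2 lensbased            3.282350        0.6973301
res$stages$calibration
#>       step1       step2       step3       step4
#> 6.130307660 6.130307660 0.107524316 0.000478929
```

The run simulates a nuclei-and-stroma tissue phantom, reconstructs it from
an 8-height hologram stack, pushes a blurred, misaligned, color-distorted
copy through the camera model, calibrates it with a checker-fitted model,
registers and fuses the pair. The report says the fused image is closer to
the ground truth pixel-by-pixel (ΔE₉₄ 2.92) than the lens-based arm alone
(3.28) — fusion restores the brightness detail the low-resolution arm lost —
while both agree in region-averaged color. The calibration diagnostics show
the four steps driving the training-set mean ΔE₉₄ from 6.13 to below 0.001
for this in-model-family distortion.

A thin command-line driver wrapping the same functions is installed at
`inst/cli/dcfm.R` (`simulate`, `reconstruct`, `calibrate`, `fuse`, `run`,
`report` subcommands).

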