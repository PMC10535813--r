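---
title: "Methods: optical skin-pigment decomposition and modification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical skin-pigment decomposition and modification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

chromaderm treats a cross-polarized skin photograph as the output of a
physical image-formation process and inverts that process per pixel. The
forward model has three stages.

**Tissue optics.** Skin is modelled as two layers. The epidermis contains
melanin and transmits light by Beer-Lambert attenuation,
$T_{epi}(\lambda) = \exp(-v_m\,\epsilon_{mel}(\lambda)\,d)$, with $d$ the
epidermis thickness and $v_m$ the melanin volume fraction. The dermis
contains blood and both scatters and absorbs; its reflectance is the
semi-infinite Kubelka-Munk two-flux solution
$R_\infty = 1 + K/S - \sqrt{(K/S)^2 + 2K/S}$ with $K = 2\mu_a$,
$S = \mu_s'$. Absorption is linear in the chromophore volume fractions,
$\mu_a(\lambda) = v_m \epsilon_{mel}(\lambda) + v_h \epsilon_{hb}(\lambda)$
(concentration is folded into the effective extinction curves, since the
tissue model is parameterized purely by volume-fraction ranges), and
reduced scattering is a Rayleigh/Mie mixture
$\mu_s'(\lambda) = a\,[f_{Ray}(\lambda/\lambda_0)^{-4} +
(1-f_{Ray})(\lambda/\lambda_0)^{-b}]$. The total skin reflectance is
$R(\lambda) = T_{epi}(\lambda)^2 R_{dermis}(\lambda)$: light crosses the
epidermis, reflects diffusely off the dermis, and crosses the epidermis
again. Cross-polarized acquisition removes the specular component, so no
surface reflection term appears.

**Spectral image formation.** Each camera channel integrates illuminant
power times reflectance times sensor quantum efficiency over 450--750 nm,
multiplied by a per-pixel shading factor. Channels are white-balanced by
the camera's response to the illuminant itself, mapped to XYZ and then to
linear RGB, and finally gamma-encoded to sRGB.

**Inverse problem.** A small residual encoder-decoder network maps a
linear-RGB patch to three maps in $[0,1]$ -- melanin, hemoglobin, shading.
The normalized pigment values are affine-mapped onto the physiological
volume-fraction ranges (melanin 1.3--43%, hemoglobin 2--7%) and re-rendered
through the forward model; training minimizes the masked mean squared
error between input and reconstruction. No pigment ground truth is used:
the physics is the supervision.

## Parameters and defaults

| parameter | default | units | notes |
|---|---|---|---|
| wavelength grid | 450--750, step 5 | nm | 61 samples, trapezoid quadrature |
| melanin volume fraction | 0.013--0.43 | -- | normalized map 0/1 maps to lo/hi |
| hemoglobin volume fraction | 0.02--0.07 | -- | blood volume fraction |
| epidermis thickness | 0.06 | mm | Beer-Lambert path, single pass |
| hemoglobin oxygenation | 0.75 | -- | oxy/deoxy mixture of the extinction curve |
| scattering `a`, `b`, `f_Ray`, `lambda0` | 4.0 /mm, 1.3, 0.4, 500 nm | | Rayleigh/Mie mixture |
| LUT grid | 64 x 64 | nodes | bilinear interpolation, inputs clipped to ranges |
| network | 16 base channels, depth 4 | | sigmoid-bounded 3-map head |
| training | Adam, lr 1e-3 cosine-annealed to 5e-5, 1500 steps | | masked MSE loss, seeded |
| checkpoint threshold | 35 | dB | running masked PSNR |

The reflectance LUT bakes the whole spectral pipeline (everything except
shading and gamma) into a grid over (melanin, hemoglobin) volume
fractions. Rendering a pixel is then a bilinear lookup times shading,
which is cheap and piecewise-differentiable -- the analytic cell gradients
are what backpropagation consumes. At the default 64-node grids the
bilinear interpolant agrees with brute-force spectral integration to well
under 1e-3 per channel (verified in the test suite), and exactly (1e-9)
at the nodes.

## Numerical and design choices

**Spectral data.** The shipped eumelanin, oxy-/deoxyhemoglobin, and D65
curves are smooth synthetic approximations to published data (power law
for melanosome absorption; splines through standard anchor values for
hemoglobin and D65), marked `_synthetic` in their filenames. The sensor is
an idealized three-Gaussian quantum-efficiency triple; user-supplied
two-column files can replace any of these. The CIE 1931 observer used to
fit the camera matrix is an analytic multi-Gaussian approximation.

**White-point preservation.** The camera-RGB-to-XYZ matrix is fitted by
least squares from the sensor responses to the observer responses under
the configured illuminant, then adjusted so that the combined
camera-to-linear-RGB chain maps camera white exactly to (1,1,1). Together
with white balance defined as the reciprocal response to a perfect
reflector, this makes the white-balance closure property hold to machine
precision rather than approximately.

**Epidermis thickness.** With the literature melanosome absorption scale
(about 690 /cm at 500 nm, falling as $\lambda^{-3.48}$), a Beer-Lambert
epidermis cannot simultaneously render the 1.3% range minimum as warm
very-light skin (which needs a large thickness-extinction product) and
keep the 43% maximum optically resolvable (which needs a small one). The
default of 0.06 mm favours resolvability: the full melanin range maps to
distinct colors, which conditions the inverse problem well. The
consequence is that fully desaturating melanin renders near-achromatic
(blue-green balanced) skin, so the individual typology angle saturates
near 90 degrees rather than in the 40--50 range a warmer reference
reflectance table would give. Users who prefer warm light-skin renderings
at the expense of the dark end can set `epidermis_thickness_mm = 0.25`,
the conventional thickness of table-based two-layer models.

**Patch blending.** Full images are processed in fixed patches with a
15-px overlap. Recombination uses distance-to-border crossfade weights
normalized per pixel, an exact partition of unity; across a standard
overlap band between two patches the normalized profile is an exactly
linear ramp, so outputs that differ by a constant blend without a visible
seam. The last patch along each axis is anchored to the image border, and
the weights adapt automatically to the resulting wider overlap. Inputs
smaller than a patch are reflect-padded and cropped back after blending.

**Loss masking.** The reconstruction loss is computed over skin pixels
only. Non-skin pixels are zeroed by the mask overlay before the network
sees them, so they are identically zero in both input and reconstruction;
masking simply removes these trivial pixels from the average. The
decomposition is therefore mask-equivariant: pixels outside the mask
cannot influence maps inside it.

**Degenerate inputs.** Optical density caps at 4 for zero intensities;
E.I2 excludes zero-green pixels with a warning; LUT lookups clip volume
fractions to the grid ranges; map values outside $[0,1]$ are clipped with
a warning at the rescale stage. PSNR of identical images is reported as
`Inf`.

**Optimizer and head.** Adam (lr 1e-3) and a sigmoid-bounded output head
are unstated in the original formulation of this training scheme; both
are conventional and configurable. The shading head receives no direct
supervision; a total-variation regularizer is available but off by
default. Random-crop augmentation (78 to 64 at desk scale, mirroring 310
to 256 at full scale) is the only augmentation.

## The synthetic-skin generator

The generator stands in for clinical data. Pigment maps are Gaussian
random fields: white noise smoothed by circular FFT convolution with a
Gaussian kernel whose sigma is half the requested correlation length (so
the empirical correlogram e-folds at the requested length), scaled to a
given standard deviation around subject-level base values and clipped to
$[0,1]$. Shading is an independent low-frequency field squashed into
$[0.5, 1]$. Hyperpigmented regions are raised-cosine-edged plateau blobs
added to the chosen pigment map, with an interior region mask and an
annular surround mask of untouched skin, so the designed region-surround
contrast equals the blob gain by construction.

The default population was fixed once from the study-cohort description
the pipeline emulates (skin tones concentrated mid-scale with a full
light-to-dark spread; hemoglobin narrower and lower): base melanin
$N(0.30, 0.13)$ clipped to $[0.05, 0.70]$ and base hemoglobin
$N(0.45, 0.15)$ clipped to $[0.10, 0.90]$ in normalized units, field sd
0.08 with correlation length 8 px.

What the generator does *not* emulate: facial geometry, hair, sensor
noise, chromatic aberration, specular residue, subsurface-scattering blur,
or any mismatch between the assumed and the true image-formation model.
Synthetic images are rendered by the very forward model the network
inverts, so passing tests demonstrate that the self-supervised framework
recovers the generating parameters when the physics is correct -- they do
not demonstrate robustness to model mismatch on real photographs.

## Problem sizes

The package's study conditions are deliberately small: 64 x 64 patches,
a 16-channel depth-4 network, 200 synthetic training patches, 1500
optimizer steps, 20 held-out subjects, and 10 blob subjects per pigment
for the contrast sweeps. These sizes exercise every component of the
framework -- spectral LUT, differentiable rendering, patch blending,
self-supervised training, modification, and quantification -- at desktop
cost. A full-scale clinical deployment (256-px patches, a ResUNet++-class
network, hundreds of GPU epochs, clinical reference maps) is out of
scope.

## Known limitations

* The two-flux Kubelka-Munk stand-in is not the reference reflectance
  table of the literature it replaces; absolute index values and the ITA
  saturation level depend on it (see the epidermis-thickness note above).
* Reconstruction loss constrains the three maps very unevenly. The
  residual left after optimally re-adjusting melanin and shading is a
  shallow (near-quadratic) function of the hemoglobin error, so at the
  reconstruction quality reachable in a desktop training budget the
  hemoglobin map is only weakly pinned: melanin and shading maps recover
  with high per-pixel correlation to the generator's ground truth while
  hemoglobin does not. Driving the loss toward interpolation (the valley's
  unique minimum is at the truth) would recover it in principle; within
  the desk-scale budget it stays the method's weakest output, consistent
  with the general difficulty of discriminating pigment maps from color
  images alone.
* The melanin index responds weakly to hemoglobin (blood absorbs some
  red), so "independence" of the two adjustments is approximate, as it is
  for the color-image indices themselves.
* Training at desk scale is CPU-bound R code; it is reproducible and
  budgeted in minutes, not intended for full-resolution photographs.
* Hemoglobin oxygenation is a fixed mixture; venous/arterial spatial
  structure is not modelled.
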