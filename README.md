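# chromaderm

Physics-based discrimination and numerical modification of skin pigments in
cross-polarized photographs.

Skin tone and localized pigmentation are governed by two chromophores:
melanin in the epidermis and hemoglobin in the dermal blood supply.
chromaderm decomposes a skin image into per-pixel **melanin**,
**hemoglobin** and **shading** maps by inverting a spectral forward model
of skin image formation — no pigment ground truth is needed. The maps can
then be altered with numerical control (uniform shifts for overall skin
tone, multiplicative scaling for pigmented-region contrast) and re-rendered
into modified images, with the change quantified by standard color-image
indices. It is aimed at skin-imaging researchers who need controllable,
physically grounded pigmentation edits or labelled synthetic data.

## The model

Two-layer tissue optics: the epidermis transmits by Beer–Lambert
attenuation with melanin as absorber, and the dermis reflects by the
semi-infinite Kubelka–Munk two-flux solution with blood as absorber,

```
R(λ) = T_epi(λ)²·R_dermis(λ),   T_epi = exp(−v_m ε_mel(λ) d),
R_∞ = 1 + K/S − sqrt((K/S)² + 2K/S),   K = 2 μ_a,  S = μ_s′(λ),
μ_s′(λ) = a [f_Ray (λ/λ0)⁻⁴ + (1−f_Ray)(λ/λ0)^(−b)]
```

over 450–750 nm. Camera channels integrate illuminant × reflectance ×
quantum efficiency, are white-balanced against the illuminant, and pass
through camera→XYZ→linear-RGB matrices and sRGB gamma. The whole spectral
chain is baked into a 64×64 reflectance lookup table over the
physiological volume-fraction ranges (melanin 1.3–43 %, hemoglobin
2–7 %), making per-pixel rendering differentiable and cheap. A residual
encoder–decoder network is trained **self-supervised**: it predicts the
three maps, the renderer reconstructs the patch, and the masked MSE
between input and reconstruction is minimized. Modifications are
quantified by the individual typology angle
`ITA = arctan((L* − 50)/b*)·180/π`, the melanin index `M.I = OD_R`, and
the erythema indices `E.I1 = OD_G − OD_R` (Diffey) and
`E.I2 = I_B·I_R/I_G` (Jacovels), with region-vs-surround contrast for
pigmented areas.

## Worked example

```r
library(chromaderm)

lut <- default_lut()                       # spectral pipeline -> lookup table

# synthetic cohort: 40 training patches and one test subject
train <- lapply(1:40, function(i) {
  s <- generate_subject(random_subject_spec(i), lut, shape = c(64, 64))
  srgb_to_linear(s$image$data)
})
tr <- train_self_supervised(train, lut, model_config(seed = 1, steps = 300))

subj <- generate_subject(random_subject_spec(999), lut, shape = c(64, 64))
maps <- decompose_image(subj$image, NULL, tr$model)

# reconstruction fidelity and skin tone of the subject
psnr(render_maps(maps, lut), srgb_to_linear(subj$image$data))
ita(subj$image)

# darken the skin tone: add +0.4 to the melanin map and re-render
mod <- generate_modified_image(subj$image, NULL, tr$model,
                               modification_spec("additive",
                                                 delta_melanin = 0.4), lut)
ita(mod)
```

On this 300-step toy run the reconstruction PSNR printed is 32.4 dB, the
subject's ITA is 50.6° (light skin), and the melanin-shifted image's ITA
is −29.9° — adding melanin darkens the rendered skin, exactly the
monotone response the modification is designed to have. (The package's
full desk-scale configuration in `scripts/acceptance.R` trains longer —
1500 steps on 200 patches — and reaches held-out PSNR above the 35 dB
checkpoint threshold.)

## Scope

Specular reflection is out of scope by construction (cross-polarized
input). Skin segmentation is accepted as an input mask. The package's
methods vignette (`vignettes/pigment-decomposition-methods.Rmd`)
documents the model assumptions, parameter defaults, the synthetic-data
generator, and known limitations.
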