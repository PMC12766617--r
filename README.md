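# cdtidenoise

Accelerating cardiac diffusion tensor imaging (cDTI) by reducing breath-hold
repetitions, with tensor-space deep-learning de-noising — exercised end to
end on synthetic left-ventricle phantoms.

## The problem

cDTI probes myocardial microstructure by acquiring diffusion-weighted images
(DWIs) at several b-values (here 0, 150, 600 s/mm²) along six gradient
directions, fitting a symmetric 3×3 diffusion tensor per voxel, and deriving
four quantitative maps from its eigensystem:

- **MD** (mean diffusivity): `MD = (λ₁ + λ₂ + λ₃)/3`
- **FA** (fractional anisotropy):
  `FA = √(3/2) · √(Σᵢ(λᵢ − MD)²) / √(Σᵢλᵢ²)`
- **HA** (helix angle): the angle of the primary eigenvector's projection
  onto the circumferential–longitudinal plane, varying roughly linearly from
  endocardium (+60°) to epicardium (−60°)
- **E2A** (second-eigenvector / sheetlet angle), reported as an absolute
  angle in [0°, 90°]

One STEAM repetition (one b₀ plus 6 DWIs) takes 18 heartbeats; clinical
protocols average many repetitions for SNR, which costs ~8 min per slice and
phase — 16 min per slice for two cardiac phases and ~192 min for whole-heart
coverage. Reduced breath-hold regimes (5BH/3BH/1BH = fewer repetitions)
save time but inflate noise, which biases the maps (most visibly FA).

This package implements the full acceleration framework:

1. **Synthetic LV phantoms** — annular short-axis geometries with analytic
   ground-truth tensor fields (prescribed MD/FA/HA/E2A), infarct sectors and
   mirrored-chirality (situs inversus) variants.
2. **DWI simulation** — the clinical repetition structure (12 b₀ / 10 b₆₀₀ /
   2 b₁₅₀ on average), Rician magnitude noise, breath-hold subset regimes
   and repetition averaging.
3. **Tensor fitting** — log-linear least squares (LLS) per voxel, no
   positivity projection, plus the two network-conditioning schemes
   (×1500 scaling; per-channel z-scoring).
4. **Tensor-space de-noising** — a U-shaped windowed-attention generator
   with residual learning (identity at initialization), a PatchGAN critic,
   Wasserstein gradient-penalty adversarial training, repetition-subset /
   rotation / content-aware-crop augmentation, patient-level 80:10:10
   splits and bagging ensembles. The networks (forward and backward passes)
   are implemented natively in R with two C++ kernels for the convolution
   gathers and window attention; every gradient is finite-difference
   checked in the test suite.
5. **Evaluation** — wraparound angular error (MAAE), masked map errors,
   median [IQR] cohort summaries, transmural HA profiles, three-zone FA
   analysis, infarct-remote ΔMD contrast and patch-level model comparison.

## Worked example

```r
library(cdtidenoise)

# a phantom subject and its simulated full acquisition at SNR 25
ph  <- lv_phantom(grid_shape = c(64, 64))
ser <- simulate_dwi(ph$tensor, ph$s0, make_protocol("full"),
                    noise_sigma = 1/25, seed = 7)

# full-repetition reference fit vs single-breath-hold fit
avg_full <- average_repetitions(ser)
ref <- fit_lls(avg_full, build_design_matrix(avg_full), ph$geometry$myo_mask)
sub <- regime_subset(ser, "1BH", "first")
avg_1bh <- average_repetitions(sub)
one <- fit_lls(avg_1bh, build_design_matrix(avg_1bh), ph$geometry$myo_mask)

fr <- ph$orientation$frame
map_errors(cdti_maps(one$tensor, fr), cdti_maps(ref$tensor, fr),
           ph$geometry$myo_mask)
#>    ha_maae  e2a_mae       md_mae     fa_mae
#> 1 7.421284 13.81596 6.581217e-05 0.06432995
```

The single-breath-hold fit is ~7.4° of helix-angle error and ~0.064 of FA
error away from the full-repetition reference — the gap the de-noiser is
trained to close. The end-to-end study (cohort generation, training a tiny
2-member ensemble, held-out evaluation) runs in a few minutes on one CPU:

```r
st <- run_denoise_study(seed = 1)
round(st$reduction_pct, 1)
#> ha_maae e2a_mae  md_mae  fa_mae
#>    36.4    35.3     7.6    32.9
st$sit_ha_ratio
#> [1] 1.21
```

i.e. the de-noised 1BH maps cut the median HA and FA errors by roughly a
third relative to plain LLS, and a model trained only on normal-chirality
phantoms degrades only mildly (ratio ≤ 1.5) on mirrored (situs inversus)
anatomy.

A thin CLI (`inst/cli/cdti`) exposes `simulate`, `fit`, `train`, `denoise`,
`evaluate` and `run` verbs over YAML configs; `run_experiment()` writes all
artifacts as NIfTI volumes with JSON sidecars plus a `report.json`.

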