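---
title: "Methods: phantom construction, tensor fitting and tensor-space de-noising"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom construction, tensor fitting and tensor-space de-noising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, numerical choices and
limitations behind `cdtidenoise`. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The pipeline in one paragraph

Cardiac DTI estimates a symmetric 3×3 diffusion tensor per myocardial voxel
from magnitude diffusion-weighted images (DWIs) and summarizes it as four
maps: mean diffusivity (MD), fractional anisotropy (FA), helix angle (HA)
and absolute second-eigenvector angle (E2A). Acquisitions repeat each
(b-value, direction) image many times and average them for SNR; cutting
repetitions (the 5BH/3BH/1BH reduced breath-hold regimes) saves scan time
but inflates noise in the fitted tensors and biases the maps. The package
simulates that entire chain on analytic left-ventricle phantoms and trains a
tensor-to-tensor de-noising network to map noisy reduced-repetition
least-squares tensors toward full-repetition reference tensors.

## 2. Phantom model

**Geometry.** A short-axis slice is modeled as an annulus on a regular
grid: voxel centers at integer coordinates (0-based, row-major), a
continuous LV center, blood pool at radius `rho < r_endo`, myocardium at
`r_endo <= rho <= r_epi`, and transmural depth
`(rho − r_endo)/(r_epi − r_endo)`. The slice is treated as a single 2-D
plane (an 8 mm slice collapsed to its mid-plane), matching the per-slice
2-D processing of clinical pipelines. The coordinate frame is fixed once:
x = column direction, y = row direction, z = slice normal; the local triad
is radial `r` (in-plane unit vector from the LV center), circumferential
`c = z × r`, longitudinal `l = z`. One explicit convention is required for
HA/E2A to be testable; any consistent choice is equivalent, and the chosen
one is validated by exact round-trips (see §5).

**Orientation.** HA varies linearly with depth between an endocardial and
an epicardial value (defaults +60° to −60°, the textbook healthy pattern);
E2A is constant (default 20°). A mirrored-chirality flag negates HA
everywhere, emulating the reversed helical pattern of situs inversus
totalis. These defaults are conventional values for healthy myocardium,
not estimates of any particular cohort.

**Tensors from maps.** Per voxel we need eigenvalues
`λ₁ ≥ λ₂ ≥ λ₃ > 0` with mean MD and the standard FA closed form, plus a
third constraint to pin the triple; we fix the secondary-anisotropy ratio
`λ₂/λ₃ = 1.5`, which keeps the second eigenvector non-degenerate so E2A is
well defined. Writing `λ₃ = t`, FA determines the second moment `Σλᵢ²`
(because `FA² = (3/2)(1 − (Σλ)²/(3Σλ²))`), and the constraint set reduces
to a quadratic in `t` solved in closed form; the root on the admissible
branch (`λ₁ ≥ λ₂`) is taken. FA = 0 short-circuits to the isotropic triple.
For a given ratio `k` the attainable positive FA has floor
`(k−1)/√(2k²+1)` (≈ 0.213 at k = 1.5); prescriptions below it are rejected
rather than silently clipped. Eigenvectors are assembled from the local
frame: `e₁ = cos(HA)·c + sin(HA)·l`, `e₂ = sin(E2A)·m + cos(E2A)·k` with
cross-myocyte axis `m = r` (since `e₁ ⊥ r` by construction) and in-wall
axis `k = e₁ × m`. This makes phantom construction the exact inverse of the
map derivation.

**Infarcts.** A lesion is an angular sector whose voxels are rebuilt with
lesion MD/FA while keeping each voxel's eigenvectors, so orientation is
preserved and only magnitude/anisotropy change; remote voxels are returned
bit-identical. Defaults (lesion 1.25×10⁻³, remote 1.05×10⁻³ mm²/s) follow
reported acute-infarct contrasts, giving ΔMD = 0.20×10⁻³ mm²/s by
construction.

**Cohorts.** Subjects draw geometry and tissue parameters from narrow
uniform ranges: `r_endo` 0.13–0.17 and wall thickness 0.13–0.19 of the grid
side, ±2-voxel center jitter, HA endo 50–70°, HA epi −70…−50°, E2A 10–30°,
MD 0.9–1.1×10⁻³ mm²/s, FA 0.40–0.50. The ranges are a plausible spread of
healthy anatomy at the 2.8 mm-class resolution the 64-grid field of view
represents, and they keep every myocardium inside a 48×48 crop window.

## 3. Acquisition simulation

The protocol mirrors the clinical repetition structure: per full
acquisition, 12 b₀ repetitions, 10 repetitions of each of six b = 600
directions and 2 of each b = 150 direction (84 images). The six-direction
scheme is the classic normalized-(1,1,0) permutation set, which together
with b₀ spans tensor space (design rank 7); the scheme is a fixed package
constant so results are reproducible. Reduced regimes keep the stated
repetition counts — 5BH = (4, 4, 1), 3BH = (2, 2, 1), 1BH = (1, 1, 0) — by
taking the first repetitions of each group, and training additionally uses
the central and final blocks of the same acquisition, tripling the training
pairs.

Signals follow `S = S₀·exp(−b·gᵀDg)` with Rician magnitude noise
`√((S+n₁)² + n₂²)`, `n₁,n₂ ~ N(0,σ²)`. Each image draws from a
counter-based substream of the master seed (`seed + 1000003·i`), so an
image's noise depends only on its identity and the series is bit
reproducible under subsetting. SNR is defined as `S₀/σ` on b₀; the study
default σ = 1/25 makes single-repetition data visibly noisy while keeping
log-linear fitting stable. No motion, eddy-current, EPI-distortion or
parallel-imaging effects are simulated — phantom noise is purely thermal,
which is the main gap between these tests and clinical data (§8).

## 4. Tensor fitting and normalization

Averaged images enter an ordinary least-squares fit of the log-signal on
the design `[1, −b·gx², −b·gy², −b·gz², −2b·gx·gy, −2b·gx·gz, −2b·gy·gz]`;
the intercept exponentiates to S₀ and the remaining coefficients are the
tensor. The fit is unweighted (plain LLS) by design; weighted or robust
variants are out of scope. No positivity projection is applied anywhere —
noisy voxels may carry negative eigenvalues, and FA may exceed 1 there.
Voxels with any non-positive averaged signal are excluded, zero-filled and
counted (the log is undefined; the choice to exclude rather than clip is
ours). Background is handled by mask-driven fitting rather than intensity
thresholding.

Two conditioning schemes prepare tensors for the network: multiplying all
six channels by 1500 s/mm² (bringing typical myocardial values into
roughly [−1, 1]), or per-channel z-scoring with statistics fitted on the
training split. Outside-mask voxels are zeroed in normalized space so
non-cardiac regions carry no signal. The desk-scale study uses the scale
mode; z-scoring is implemented and tested.

## 5. Map derivation and its conventions

Eigen-decomposition is per voxel, eigenvalues descending, eigenvector signs
fixed (first non-negligible component positive) for cross-platform
determinism. HA flips `e₁` so its circumferential component is
non-negative, then takes `atan2(e₁·l, e₁·c)` in (−90°, 90°]; E2A projects
`e₂` onto the cross-myocyte plane and folds `|atan2(e₂·m, e₂·k)|` into
[0°, 90°]. Degenerate cases are flagged, not repaired: exactly-radial `e₁`
(HA undefined), `λ₂ = λ₃` (E2A undefined), all-zero tensors (FA set to 0).
The deciding property is the exact round-trip: maps computed from a built
phantom reproduce the prescribed MD/FA/HA/E2A to < 10⁻⁶ at every myocardial
voxel, and quarter-turn rotation of the field (with tensor reorientation)
commutes with map computation exactly. These two tests pin the conventions
against each other, which is the strongest check available when no external
formula is normative.

## 6. The de-noiser

**Generator.** A U-shaped windowed-attention network acting on 6-channel
tensor grids: 3×3 input convolution to width C; attention blocks at full
resolution; 2×2 stride-2 down-convolution to 2C; attention blocks at half
resolution; 2×2 transposed-convolution up, skip concatenation and 1×1
fusion; attention blocks at width C; zero-initialized 3×3 output projection
added to the input (residual learning). Each block is
`x + MSA(LN(x))` then `x + MLP(LN(x))` with non-overlapping window
attention (window 8, softmax over w² tokens) and a GELU MLP
(sigmoid-form approximation). Zero-initializing the output head makes the
untrained generator exactly the identity — a testable contract that also
stabilizes early training. Window size must divide the feature map at both
resolutions (64/32 and 128/64 both work with window 8). Internals (heads,
MLP ratio, depths) are presets, not contracts: the normative surface is
6-in/6-out, spatially preserving, windowed attention, U-shaped, residual.
The `tiny` preset (C = 12, one block per stage, ~1.2×10⁴ parameters) is
used for all desk-scale experiments; the `reference` preset reproduces the
~4×10⁷-parameter class of the full-scale model and exists as a
configuration only (its parameter count is computed analytically, not
allocated).

**Critic and adversarial loss.** A PatchGAN-style critic (three 4×4
stride-2 leaky-ReLU convolutions, 3×3 projection to one channel) emits a
16×16 score grid for 128×128 input — per-patch unbounded Wasserstein
scores, no squashing. Losses follow the gradient-penalty formulation:
`critic = mean(D(fake)) − mean(D(real)) + λ_gp·mean((‖∇x D(x̃)‖−1)²)` on
random convex interpolates, `generator += −λ_adv·mean(D(fake))`. Defaults
λ_adv = 0.01, λ_gp = 10, one critic step — the literature's standard
values, since the full-scale recipe does not pin the MAE/adversarial
weighting. The penalty's parameter gradient needs a second derivative; it
is computed as a central finite difference of the critic's parameter
gradient along the direction `v ∝ (‖g‖−1)·g/‖g‖`, which is exact for the
piecewise-linear critic away from activation kinks and costs two extra
backward passes. The desk-scale study trains with λ_adv = 0 (pure MAE
regression): at tiny scale and short schedules the adversarial term adds
variance without measurable map-error benefit, and the supervised path is
the one the acceptance properties quantify. Adversarial training is fully
implemented and smoke-tested.

**Implementation note.** No deep-learning framework is used: layers carry
hand-derived backward passes in R, with two C++ kernels (im2col/col2im and
batched window attention) for the interpreter-bound inner loops. Every
layer and both full networks are validated against central finite
differences in the test suite; that check, not any framework, is the
correctness anchor.

**Training.** AdamW (decoupled weight decay, default 0) with the published
full-scale hyperparameters as defaults: lr 10⁻⁴, β₁ = 0.9, β₂ = 0.999, 500
epochs, batch 8, MAE objective, checkpoint at the lowest validation loss,
everything seeded (initialization, shuffling, augmentation draws; identical
seeds give identical loss curves). The desk-scale preset overrides the
schedule — lr 3×10⁻³, 8 epochs, batch 4 — because a 10⁴-parameter network
on ~120 training pairs sits in a completely different optimization regime
from a 4×10⁷-parameter network on thousands of images; the small batch
raises the update count per pass, and the higher rate is stable for the
tiny model. Training pairs are 48×48 content-aware crops (guaranteed to
contain the full myocardium) with random exact 90° rotations, both applied
with proper tensor reorientation `D′ = R D Rᵀ`; reorientation under
rotation is a physical necessity even where augmentation recipes omit it —
rotating the grid without rotating the tensors would corrupt the targets.

**Ensemble.** Five independently seeded members at full scale; the
desk-scale study uses two (the smallest ensemble that still exercises
bagging; the convexity property `MAE(mean) ≤ mean(MAE)` holds for any
size). Predictions are averaged elementwise in normalized space, then
denormalized.

## 7. The synthetic study and its problem sizes

`run_denoise_study()` is the end-to-end experiment: a 50-subject training
cohort split 80:10:10 at the patient level (40 train / 5 validation / 5
test), full 84-image acquisitions at SNR 25, full-repetition LLS fits as
reference targets (matching the practice of training toward the
best-available fit rather than unobservable truth), 1BH first/central/last
subsets as the three noisy views per subject (120 training pairs), a tiny
two-member ensemble, and evaluation on an independent 12-subject held-out
cohort plus 3 mirrored-chirality subjects — errors always measured against
each subject's own full-repetition reference maps. These sizes are the
package's chosen desk-scale conditions: large enough for stable medians
(12-subject evaluation), small enough that the whole study is minutes on a
single CPU. The noise-bias study uses 20 replicates, the smallest count at
which the FA-error ordering across 5BH/3BH/1BH is stably strict.

The supporting analyses follow the clinical playbook: transmural HA
profiles are rays from the LV center through each epicardial border pixel,
bilinearly sampled at quarter-voxel steps, blood-pool samples discarded,
surviving segments length-normalized and median-aggregated (both mean±sd
and median/IQR bands are exposed, since the band definition is a matter of
taste); FA is summarized in three equal-depth zones; infarct contrast is
the lesion-minus-remote mean MD. Profile endpoints inherit a half-voxel
partial-volume bias — map values live at voxel centers, so the first/last
samples of a ray average tissue from slightly inside the boundary; the
prescribed-line oracle is therefore asserted on interior wall positions.

## 8. Numerical choices, degenerate inputs, limitations

- Quantiles everywhere are linear-interpolation (R type 7); IQR = Q3 − Q1.
- Patch comparison tiles are anchored at the mask bounding box; a tile
  qualifies with ≥ 1 masked voxel; ties count against the "better" model.
- Repetition-subset rule: for R available and n requested, central starts
  at `floor((R−n)/2)`; subsets of R = 3n repetitions are disjoint and
  covering.
- Rank-deficient protocols, empty masks/sectors/zones, negative σ or
  penalty weights, out-of-range angles, and non-finite tensors all fail
  fast with descriptive errors rather than propagating.
- Significance testing is deliberately not re-implemented: per-subject
  error tables are returned so standard tests (e.g. `wilcox.test`) apply
  directly.
- What passing these tests does **not** show: the phantoms have no motion,
  mis-registration, partial-volume mixing, susceptibility distortion or
  anatomical variability beyond smooth parameter jitter, and their noise is
  exactly Rician; de-noising gains measured here bound what the same
  architecture could do on clinical data only loosely. The 2-D single-slice
  phantom also cannot probe through-plane fiber dispersion, papillary
  muscles or wall-thickness variation.
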