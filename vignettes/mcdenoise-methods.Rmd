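---
title: "Methods: simulating and denoising Monte Carlo fluence volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and denoising Monte Carlo fluence volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Monte Carlo (MC) photon transport is the reference method for modeling
near-infrared light propagation in turbid media such as biological tissue.
Because a simulation averages the stochastic trajectories of photon
packets, its voxel-wise output carries shot noise: raising the photon count
tenfold raises the voxel signal-to-noise ratio (SNR) by roughly 10 dB, at
ten times the cost. `mcdenoise` implements the alternative route: learn the
noise structure of low-photon fluence volumes with a residual 3D
convolutional network and remove it, obtaining image quality equivalent to
simulating many times more photons. The package contains every stage needed
to study this trade-off end to end on a single CPU: a random phantom
generator, a voxelated MC forward solver, dynamic-range transforms, the
cascaded denoiser with its training loop, and a volumetric evaluation
suite.

## The forward model

### Phantoms

A simulation domain is an isotropic integer label grid plus a table mapping
each label to optical properties: absorption `mua` (mm^-1), scattering
`mus` (mm^-1), scattering anisotropy `g`, and refractive index `n`. Random
domains combine 0 to 4 inclusions — convex polyhedra spanned by 4 to 10
points drawn uniformly (by area) on a random sphere, or ASCII letters
rendered in 2D, extruded, and posed with a uniform random 3D rotation —
inside a homogeneous background. Each shape mask is multiplied by a
power-of-two coefficient before accumulation, so every overlap pattern of
shapes receives its own unique label with independently sampled properties:
intersections become new inclusions rather than ambiguous mixtures.

Per-label properties are drawn as `mua = |N(0.01, 0.05)|` mm^-1, `g ~
U[0.9, 1)`, reduced scattering `musp = |N(1, 1)|` mm^-1 with `mus =
musp/(1 - g)`, and `n ~ U[1, 10]`. The refractive-index range is far wider
than real tissue (n of roughly 1.33 to 1.5) but is kept as the generator
default because it exercises strong internal refraction; `n_range` narrows
it when realism matters more than stress coverage.

Two rendering choices were genuinely open and are fixed as follows. Voxel
membership uses the voxel-center rule (a voxel belongs to a shape iff its
center at `(i - 0.5) * h` lies inside), the unambiguous convention of voxel
MC codes. Letter glyphs are rasterized through the R graphics engine
(monospace family on a cairo canvas, thresholded at 50% coverage) rather
than a bundled font file; the observable contract — a binary 2D glyph mask
extruded to a slab — is unchanged, and the rendering path is exercised
directly by the tests.

### Photon transport

The solver propagates photon packets with continuous weights. Scattering
lengths are sampled exponentially against the local `mus` with voxel-by-
voxel traversal, deflection cosines follow the Henyey–Greenstein inverse
CDF, and absorption attenuates the weight continuously
(`exp(-mua * l)` per ray segment). Fluence is scored as deposited energy
per voxel divided by `mua * V * N_photons`; in `mua -> 0` voxels the
equivalent path-length estimator `w * l / (V * N_photons)` is used, so the
two estimators agree in the limit and the output is finite everywhere.
Time-of-flight accumulates as `l * n / c`; contributions stop at the
continuous-wave time gate. Refractive-index mismatches — internal or at the
domain boundary against air (`n = 1`) — are handled with Snell/Fresnel
decisions at axis-aligned voxel faces; sub-voxel surface normals are out of
scope. Russian roulette (threshold 1e-4, survival 0.1) terminates
low-weight packets unbiasedly and is disabled wherever energy conservation
is audited; with roulette off, launched weight equals absorbed + escaped +
time-gated + residual weight to 1e-6 relative on every run.

Each photon owns a counter-based RNG stream obtained by hashing (run seed,
photon index) through a 64-bit finalizer, so a run's output is a pure
function of its seed regardless of scheduling. One subtlety is worth
recording: per-photon streams must *not* be spaced arithmetically with the
generator's own internal increment, or consecutive photons replay shifted
copies of the same draw sequence and the inter-photon correlation silently
breaks the `1/sqrt(N)` scaling of voxel variance. The implementation hashes
the index to a pseudo-random stream offset and the shot-noise property (10
dB SNR gain per tenfold photons) is asserted by the acceptance suite.

The solver was validated against the closed-form continuous-wave diffusion
Green's function `phi(r) = exp(-mu_eff r) / (4 pi D r)`,
`D = 1/(3 (mua + musp))`, on a homogeneous domain: radially averaged MC
fluence agrees within 15% throughout the diffusive regime (the acceptance
suite re-runs this check).

Three cube benchmarks are built in: a homogeneous 100 mm cube (`b1`), the
same cube with a centered 40 mm cubic absorber (`b2`), and with a
refractive inclusion (`b3`), each linearly scalable for desk-scale work.
Standard references for their optical coefficients are external, so the
package ships configurable defaults (background `mua = 0.005`, `musp = 1`,
`g = 0.9`, `n = 1.37`; absorber with tenfold `mua`; refractive inclusion
with `n = 1`); no quantitative check depends on their exact values.

## Dynamic-range handling

Fluence spans many decades, which defeats denoisers designed for bounded
images. Volumes are compressed with `y = ln(c x + 1)` before the network
and inverted with `x = (e^y - 1)/c` afterwards. The constant `+1` keeps the
transform non-negative; the gain `c` selects which decades are amplified.
Following the dual-gain inference scheme, each volume is denoised twice —
once at `c = 1` and once at `c = 1e7` — and merged voxel-wise: voxels whose
*original* fluence exceeds 0.03 take the low-gain result, the rest the
high-gain result. Transforms run in double precision (at `c = 1e7` a
single-precision round trip loses digits), negative log-space outputs from
a slightly overshooting network are clamped to zero before inversion, and
volumes are never normalized by a data maximum.

## The denoiser

The cascade composes two residual stages. A DnCNN-style global stage — a
stack of 3D convolutions with batch normalization and rectifiers —
predicts a spatially invariant noise map `r1(y)` which is subtracted from
the input. A UNet-style local stage (average pooling encoder, transposed-
convolution decoder, skip connections, batch normalization between the
convolution, transposed-convolution and pooling layers) then predicts the
remaining spatially varying noise `r2` of the intermediate, giving
`m(y) = (y - r1(y)) - r2(y - r1(y))`. Both stages learn in the residual
space, and the cascade is trained jointly end to end with a single loss on
the final output (stage-wise pre-training was the open alternative; joint
training is simpler and the residual parameterization keeps the untrained
model near the identity, since the final layer of each stage is initialized
near zero).

Exact layer counts are configurable because the source architecture leaves
them open; the package defaults are a global stage of depth 8, width 32,
kernel 3 (kernel 3 in the first layer as well) and a local stage of 3
scales with base width 16. The desk-scale runs in the tests use smaller
stages (depth 5 / width 8 and 2 scales / width 8). Volume borders use
replicate padding; inputs whose spatial size is not a multiple of the local
stage's stride are padded internally and cropped back, so the shape
contract holds for arbitrary sizes. Patch-tiled inference with linear
feathering is available for volumes too large for whole-volume processing
and matches the whole-volume path within 1e-3 RMS in log space on the
tested sizes. All forward/backward kernels are compiled (Rcpp) and every
gradient was verified against central finite differences.

## Training recipe

The loss is the mini-batch mean of `|F(y) - x|^n` in log space with
`n = 2` by default. Optimization uses Adam with *decoupled* weight decay
1e-4 applied to convolution weights only — never to biases or batch-norm
parameters (the exemption is asserted by a parameter-group audit test) —
a linear warm-up followed by cosine annealing to zero, and per-group
gradient-norm clipping: 2 for batch-norm parameters, 1 for everything else.
Augmentation applies, independently and each with probability 0.7, one
90-degree rotation about a random axis and one flip along a random axis,
identically to the noisy input and the clean label.

Training pairs map a low-photon volume to the highest simulated photon
level of the same phantom/source/gate, which plays the ground-truth role.
Mini-batches can optionally be built from random same-location cubic crops
of the pairs (`patch_size` in `train_config`) — the standard device of
convolutional denoiser training for multiplying effective samples and
update counts at fixed wall time; validation always runs on whole volumes.
Because the gain used at training time is not pinned down by the inference
procedure, the default policy draws each pair's gain uniformly from the two
inference gains {1, 1e7} (configurable to a fixed gain); mini-batches are
gain-homogeneous so batch-norm statistics stay on one scale. Validation
MSE/SSIM/PSNR are computed every epoch and the returned model is the
checkpoint with the best "overall" validation metrics; since that selection
rule admits several readings, the default is the rank-sum composite of
(MSE down, SSIM up, PSNR up), with single-metric alternatives available.

The reference large-scale recipe (base learning rate 1e-4, 1000 warm-up
iterations, batch 4 per device, 1500 epochs on eight accelerators) is
reproducible by configuration. The package defaults are desk-scale: 40
epochs, batch 2 to 4, base learning rate 1e-3, 20 warm-up iterations —
chosen once so that a toy cascade trained on the bundled fixture set (six
24-voxel domains at photon levels 100/1000/10000) converges in minutes on
one CPU.

## Evaluation

Global metrics are computed on log-compressed volumes: the PSNR ceiling
`Imax = 40` is defined on the transformed scale, and the published MSE
magnitudes are only consistent with transformed values; the gain used for
metric computation defaults to 1e7 and is recorded in each report. PSNR is
taken as `20 log10(Imax / RMSE)` — the printed norm expression is read as a
root-mean-square error, the standard PSNR convention. The 3D SSIM uses a
Gaussian window with `sigma_G = 5` voxels truncated at radius `3 sigma`
(renormalized, reflective borders) and constants `C1 = (0.01 L)^2`,
`C2 = (0.03 L)^2` with `L = 40`, the conventional stabilizers for a stated
dynamic range.

Local metrics start from a stack of independently seeded repetitions:
`SNR(r) = 20 log10(mu(r) / sigma(r))` per voxel, with the population
(1/N) deviation estimator, defined where both mean and spread are positive.
`delta_snr` averages the voxel-wise SNR change over the commonly valid
region (region masks can restrict it) and additionally over the effective
region improved by more than 0.5 dB. The photon multiplier
`MF = 10^(dSNR/10)` converts an SNR gain into the equivalent fold-increase
in photons under shot-noise scaling. Axis-aligned cross-section profiles of
the repetition mean and SNR support the unbiasedness check: a well-behaved
denoiser raises the SNR profile while leaving the mean profile unchanged.

## What the synthetic data does and does not show

The generator emulates the heterogeneity that matters for learning MC noise
structure — random shapes, overlaps, tissue-ranged optics, random sources
and gates — and the simulator reproduces the governing physics (shot-noise
scaling, diffusion-regime fluence, energy conservation, Fresnel effects at
voxel faces). It does not emulate anatomical atlases, curved boundaries at
sub-voxel resolution, wavelength-dependent properties, or the photon counts
of production runs: the desk-scale corpus uses 24- to 64-voxel grids and
1e2 to 1e6 photons where production studies use 100-voxel grids and 1e5 to
1e9 photons. Passing tests therefore demonstrate correctness of the
machinery and the direction and rough magnitude of the denoising effect at
desk scale, not the headline image-quality numbers of a fully trained
production model.

## Problem sizes used by the test and acceptance suites

Chosen once as the package's desk-scale study conditions: shot-noise and
SNR-gain checks use a homogeneous 30-voxel cube (1 mm voxels, `mua = 0.01`,
`musp = 1`, `g = 0.9`, `n = 1.37`) with 50 repetitions at 1e3 and 1e4
photons; the diffusion comparison uses a 50-voxel cube at 1e5 photons; the
end-to-end check trains the toy cascade on six 24-voxel fixture domains and
evaluates SNR improvement and mean-profile preservation on a held-out
scaled homogeneous benchmark with 20 repetitions.

## Known limitations

- The MC solver is a desk-scale stand-in calibrated by physics invariants,
  not bit-compatible with any production transport code; benchmark optical
  properties are configurable defaults.
- Only single-gate continuous-wave output is produced; no time-resolved
  bins, polarization, or mesh geometries.
- The denoiser trained by the test suite is deliberately tiny; its SNR
  gains are far below what a production-scale corpus and training budget
  yield.
- Batch normalization uses per-batch statistics with small batches;
  training curves are correspondingly noisy, which the checkpoint-selection
  rule mitigates but does not remove.
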