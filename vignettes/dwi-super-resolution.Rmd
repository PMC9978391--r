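---
title: "Super-resolving diffusion MRI with a residual 3D convolutional network"
author: "dwisr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-resolving diffusion MRI with a residual 3D convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwisr)
```

## The problem

Diffusion-weighted MRI (DWI) trades spatial resolution for the many
gradient directions and b-values that fiber reconstruction needs, so
clinical multi-shell acquisitions often arrive at 3&ndash;4 mm voxels.
Downstream q-space analyses &mdash; orientation distribution functions,
anisotropy maps, tractography &mdash; all inherit that coarseness.  `dwisr`
implements a learning-based restoration pipeline: a three-layer 3D
convolutional network maps an interpolated low-resolution volume onto its
high-resolution counterpart, one model per b-value shell, and the restored
volumes feed a generalized q-sampling (GQI) reconstruction of the
spin-distribution function (SDF) and its scalar indices (GFA, QA, NQA,
ISO).

The pipeline is the classic single-image super-resolution protocol:
a high-resolution volume is degraded by a factor of 3 (block averaging),
restored to the original grid by interpolation, and the network learns the
residual mapping from the interpolated image to the original.  At test
time only a low-resolution acquisition is needed.

## The network

`srcnn_spec()` describes the architecture: three 3D convolutions with
kernel edges 9, 3 and 5 voxels and 32, 16 and 1 output channels, ReLU
between layers, linear output, and "same" zero padding so output
dimensions always equal input dimensions.  The defining feature is the
residual averaging path

$$y = (1 - w)\,x + w\,f(x), \qquad w = 0.5 \text{ by default},$$

where $x$ is the interpolated input and $f$ the convolution stack.  At
$w = 0.5$ the output is the arithmetic mean of the input and the learned
feature map: the network only has to learn a correction, which keeps early
training stable (an untrained network already produces half the input, and
the final range renormalization maps that back onto the interpolated
image, so the untrained model predicts the interpolation baseline).

Design choices that were genuinely open:

* **Padding.**  "Same" zero padding rather than valid-convolution
  cropping: training targets are whole volumes of the same size, and
  zero-intensity borders behave like the air background of brain DWI.
* **Output layer is linear** (no ReLU after the last convolution),
  following the original 2D three-layer design the architecture extends.
* **Residual combination** is applied after the final convolution,
  against the interpolated image; `residual_weight` is exposed because
  other weightings are plausible readings of the design.
* **Initialization**: zero-mean Gaussian weights with standard deviation
  `init_scale = 1e-3` and zero biases, seeded and reproducible.

## Training

`fit_srcnn()` streams one (source, target) pair per iteration (batch size
is fixed at 1) through an AdaGrad/MSE loop:

$$a \leftarrow a + g^2, \qquad
  \theta \leftarrow \theta - \eta\, g / \sqrt{a + \epsilon},$$

with learning rate $\eta = 5\times10^{-4}$ and $\epsilon = 10^{-8}$.  The
per-parameter accumulator $a$ starts at zero.  A larger learning rate
makes the held-out evaluation indices oscillate late in training, which is
why the conservative default is used.  The loss is the *mean* (not sum)
of squared voxel errors so that volumes of different sizes are
comparable.  Loss is logged at every iteration and aggregated per subject
(`subject_loss()`), and weight snapshots are taken every
`checkpoint_interval` iterations plus a final one.

Training pairs (`build_pairs()`) are built per gradient entry: the
high-resolution grid, zero-padded to dimensions divisible by the factor,
is the target; the source is the target block-averaged down by 3,
restored by tricubic interpolation, and linearly renormalized onto the
target's intensity range.  The whole volume is first divided by its
global intensity maximum, so training always operates on intensities in
$[0, 1]$: AdaGrad's normalized steps move each parameter by roughly the
same amount regardless of gradient scale, so the *data* scale determines
how far the optimum is from the initialization; a fixed unit scale makes
the default learning rate meaningful across scanners and phantoms.

Images are split into three groups by diffusion weighting &mdash;
{b = 0, 1000}, {1500}, {2000} s/mm&sup2; &mdash; and one model is trained per
group (`group_by_bvalue()`).  The shells differ strongly in contrast and
SNR; a single model would have to compromise between them.  The unweighted
b = 0 image (one per subject) rides along with the b = 1000 group.

**Checkpoint selection.**  PSNR, SSIM and cosine similarity peak at
different iteration counts, so `select_best_checkpoint()` maximizes their
product, with PSNR first normalized to $[0, 1]$ by dividing every
checkpoint's average by the best checkpoint average.  Ties go to the
earlier checkpoint.

## Evaluation metrics

All metrics are *global* (whole-volume) statistics:

* **PSNR** $= 10\log_{10}(I_{max}^2/\mathrm{MSE})$ in dB.  For
  floating-point DWI no bit depth applies, so the dynamic range defaults
  to the reference maximum; identical volumes give an infinite sentinel
  that summaries exclude with a warning.
* **SSIM** is the single-window product of luminance, contrast and
  structure terms with constants $C_1 = (0.01L)^2$, $C_2 = (0.03L)^2$,
  $C_3 = C_2/2$ (at 8-bit depth: 6.5025, 58.5225, 29.26125).  Variances
  use the population (1/N) convention for bit-reproducibility.  A
  sliding-window variant is available behind `windowed = TRUE` but is off
  by default since the global form is the reference definition here.
* **Cosine similarity** of the flattened voxel vectors.
* **Intensity histograms** over a shared range (half-open bins, last bin
  closed) for qualitative distribution comparison.

Summaries report Average/Std/Max/Min over an image set.

## The phantom cohort

The study conditions are synthetic: `phantom_spec()` describes a
multi-tensor digital phantom with two orthogonal straight fiber bundles
crossing at the center of a lower axial slab, an ellipsoidal CSF-like
free-water region in the upper slab, and zero background.  Each voxel's
signal follows the multi-tensor forward model
$S = S_0 \sum_k f_k \exp(-b\,\hat g^T D_k \hat g)$ with axially symmetric
tensors, and Rician noise
$\sqrt{(S+n_1)^2 + n_2^2}$ is applied to the magnitudes.

Defaults, chosen once from standard adult-brain literature values:

| parameter | default | note |
|---|---|---|
| fiber diffusivities | 1.7/0.3 &times; 10&#8315;&sup3; mm&sup2;/s | axial/radial |
| CSF diffusivity | 3.0 &times; 10&#8315;&sup3; mm&sup2;/s | isotropic |
| CSF baseline scale | 4 &times; s&#8320; | T2 weighting at TE &asymp; 115 ms |
| shells | 1000/1500/2000 s/mm&sup2; + b = 0 | 6 icosahedral directions each |
| noise | &sigma; = 2% of s&#8320; | Rician scale |
| grid | 24 &times; 24 &times; 12 | divisible by 3 |

Two defaults deserve explanation.  First, the CSF region sits in the
upper slab rather than at the volume center: regions resolve overlaps by
priority (CSF over bundles), so a central CSF sphere would erase the
bundle crossing that the phantom exists to provide.  Second, the CSF
baseline is 4&times; brighter than tissue: diffusion acquisitions are
heavily T2-weighted, and without that factor the ISO map's
ventricle-bright contrast (free water dark in GFA, bright in ISO) cannot
arise, because equal-baseline fiber voxels retain far more high-b signal
mass than free water.

What the phantom does *not* emulate: anatomy, partial-volume gradients at
tissue boundaries, susceptibility/eddy artifacts, spatially varying coil
sensitivity, and non-Gaussian diffusion.  Passing tests on the phantom
therefore demonstrate that the pipeline's mechanics are correct and that
the network can learn the degradation model it was trained under &mdash; not
that it reaches any particular quality on clinical data.

The 6-direction shells are adequate for the super-resolution experiment,
but 90&deg; crossings cannot be resolved from 6 directions per shell;
GQI angular-recovery checks use `tessellated_gradients(level = 1)`
(21 directions per shell), a desk-scale stand-in for the 193-direction
clinical scheme.

## GQI reconstruction

`reconstruct_sdf()` computes the model-free spin-distribution function

$$\psi(\hat u) = \sum_i S_i\,
  \mathrm{sinc}\!\big(\sigma\sqrt{6 D b_i}\,(\hat g_i \cdot \hat u)\big)$$

on a subdivided-icosahedron hemisphere (321 directions at the default
level 3), with $D = 3.0\times10^{-3}$ mm&sup2;/s and sampling-length ratio
$\sigma = 1.25$.  The kernel is even, so one hemisphere suffices.
Negative SDF samples (sinc side lobes) are clamped to zero before index
computation &mdash; the SDF estimates a nonnegative spin density, and the
clamp also bounds GFA by 1.  Index maps per voxel with $n$ directions:

* GFA $= \sqrt{n\sum(\psi - \bar\psi)^2} \big/ \sqrt{(n-1)\sum\psi^2}$,
* ISO $= \min \psi$,
* QA $=$ SDF value of the top adjacency-strict local maximum minus ISO
  (zero when no peak exists),
* NQA $=$ QA normalized by the maximum QA over the masked volume.

QA is left unscaled beyond the ISO subtraction; NQA carries all
normalization.

## Numerical choices

* **Downsampling** is block averaging, which is anti-aliased and maps
  constants to themselves exactly; decimation would alias the Rician
  noise.
* **Interpolation** is separable with voxel-center alignment
  (output sample $i$ at input coordinate $(i+0.5)/3 - 0.5$) and edge
  replication; every third output sample coincides with a source lattice
  site and reproduces its value.  The cubic kernel is Keys
  ($a = -1/2$), the conventional "bicubic" baseline.
* **Range renormalization** (`normalize_range()`) maps extremes onto the
  reference bit-exactly (explicit assignment of the extreme positions, not
  just the affine map).
* **Prediction-time intensity convention.**  Inputs are divided by the
  volume-wide maximum (the interpolated volume's maximum at prediction
  time, standing in for the unknown original), which reproduces the
  training intensity convention; outputs are returned on that shared
  scale after clamping the thin negative ringing halo a convolution
  stack produces (magnitudes are nonnegative).  An explicit two-point
  min/max map onto the interpolated image's range
  (`predict(..., renormalize = "range")`) is provided for comparison,
  but is *not* the default for two measurable reasons: its anchors are
  single-voxel extremes (undershoot/overshoot outliers), and the
  interpolated image's upper intensity tail is systematically attenuated
  by exactly the smoothing the network is trained to undo &mdash;
  renormalizing toward it undoes part of the restoration and drags both
  PSNR and SSIM below values the raw network output attains.
* **Degenerate inputs**: constant volumes cannot be range-normalized
  (warning, constant at the reference minimum); all-zero SDFs yield zero
  maps with a warning; identical image pairs give the infinite PSNR
  sentinel.
* **Determinism**: every stochastic step (weight init, noise, shuffling,
  subject split) derives from explicit seeds, and seeded helpers restore
  the caller's RNG state, so experiments are bit-reproducible.

## Problem sizes

The reference experiment (`run_experiment()`, also what
`scripts/acceptance.R` reruns) uses 12 phantom subjects on
24 &times; 24 &times; 12 grids with 19 gradient entries, an 11:1
subject-level train/test split, and 8 epochs per b-value group
(roughly 530&ndash;620 iterations each with batch size 1).  Held-out PSNR
and SSIM plateau after roughly 550 iterations at this scale, so longer
training changes little.  Checkpoints are taken every 150 iterations at
this scale (the production default of 5000 matches cadences appropriate
for cohorts thousands of iterations long).

## Limitations

* The phantom is the only data source wired in; the pipeline reads real
  NIfTI + bval/bvec datasets, but no claims about clinical images are
  tested.
* One model per shell triples training cost; mixed-shell training is
  deliberately unsupported.
* The SDF implementation targets GQI only; DSI/QBI reconstructions and
  tractography are out of scope.
* The network is intentionally small; deeper variants or adversarial
  training are not provided.

## A minimal session

```{r example, eval = FALSE}
vol <- generate_phantom(phantom_spec(seed = 1))
pairs <- build_pairs(vol)
groups <- group_by_bvalue(pairs)
fit <- fit_srcnn(groups$b1500, srcnn_spec(),
                 training_control(epochs = 8, checkpoint_interval = 150))
plot(fit)             # iteration-wise MSE loss
lr <- downsample(dwi_grid(vol, 8), 3)
sr <- predict(fit, lr)           # 3x super-resolved gradient volume
metric_report(sr, dwi_grid(vol, 8))
```
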