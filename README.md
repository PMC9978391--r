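# dwisr — super-resolution of diffusion-weighted MRI with q-space index mapping

Diffusion-weighted MRI (DWI) needs many gradient directions and b-values,
so clinical multi-shell acquisitions settle for coarse 3–4 mm voxels, and
everything reconstructed from them — orientation distribution functions,
anisotropy maps, tractography — inherits that resolution. `dwisr` is an R
implementation of a learning-based restoration pipeline for people who
work with such data: it trains a compact 3D convolutional network to map
interpolated low-resolution DWI volumes onto their high-resolution
counterparts, one model per b-value shell, and reconstructs generalized
q-sampling (GQI) spin-distribution functions and index maps (GFA, QA,
NQA, ISO) from the restored data.

## The method

**Restoration network.** Three 3D convolutions (kernel edges 9/3/5,
channels 32/16/1, ReLU between layers, linear output, "same" zero
padding) with a residual averaging path:

    y = (1 − w)·x + w·f(x),   w = 0.5

where *x* is the tricubically interpolated low-resolution volume and *f*
the convolution stack. Training pairs come from the classic
super-resolution protocol — degrade a high-resolution volume by block
averaging at ratio 1/3, restore it by interpolation, and learn the
mapping back — optimized by AdaGrad (learning rate 5·10⁻⁴, batch size 1)
under a mean-squared-error loss. Images are grouped by diffusion
weighting ({b = 0, 1000}, {1500}, {2000} s/mm²) with one model per group,
and the deployed weights are the checkpoint maximizing the product of
normalized PSNR × SSIM × cosine similarity on held-out data.

**GQI reconstruction.** The spin-distribution function
ψ(û) = Σᵢ Sᵢ · sinc(σ·√(6·D·bᵢ)·(ĝᵢ·û)) is sampled on a subdivided
icosahedron hemisphere (321 directions), with scalar maps per voxel: GFA
(std/rms of ψ), ISO (min ψ), QA (top adjacency-strict peak minus ISO) and
NQA (QA normalized by its volume-wide maximum).

Because clinical DWI cohorts are rarely shareable, the package ships a
multi-tensor phantom generator (crossing fiber bundles, a CSF-like
free-water region, Rician noise) that stands in for real data in every
test and experiment; real datasets are read with the same
NIfTI + FSL bval/bvec loaders.

## A worked example

```r
library(dwisr)

vol    <- generate_phantom(phantom_spec(seed = 1))   # 24x24x12, 19 gradients
pairs  <- build_pairs(vol)                           # degrade/interpolate pairs
groups <- group_by_bvalue(pairs)

fit <- fit_srcnn(groups$b1500, srcnn_spec(),
                 training_control(epochs = 100, checkpoint_interval = 150))
print(fit)
#> <srcnn> 3-D super-resolution network
#>   layers: 9/3/5 (kernel edges), 32/16/1 (channels), ReLU between
#>   residual weight: 0.5   parameters: 39201
#>   trained for 600 iterations; final loss 9.707e-05

lr <- downsample(dwi_grid(vol, 8), 3)        # a b = 1500 volume at 8x8x4
sr <- predict(fit, lr, scale = max(vol$data))  # restored to 24x24x12
metric_report(sr, dwi_grid(vol, 8))
#> PSNR 19.97 dB | SSIM 0.8864 | cosine 0.9413 | MSE 17.34
metric_report(interpolate_up(lr, 3), dwi_grid(vol, 8))
#> PSNR 18.08 dB | SSIM 0.8183 | cosine 0.9024 | MSE 26.76
```

The model here has seen only this subject's six b = 1500 volumes (100
epochs = 600 single-pair iterations, about two minutes on one CPU), and
restores the volume roughly 2 dB and 0.07 SSIM above the tricubic
baseline.  `run_experiment()` runs the proper multi-subject version with
a held-out test subject; on the default 12-subject cohort it reports a
held-out mean of 18.95 dB / 0.874 SSIM for the network against
17.52 dB / 0.810 for tricubic interpolation.

The full pipeline — cohort generation, 11:1 subject split, per-shell
training, checkpoint selection, evaluation against the interpolation
baseline, and GQI mapping — is one call:

```r
res <- run_experiment(run_config(seed = 1))
print(res)
```

A thin command-line wrapper with `phantom` / `degrade` / `restore` /
`train` / `predict` / `evaluate` / `gqi` / `run` subcommands lives at
`inst/cli/dwisr.R`.

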