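# wmhkit

Classical computational stack for **white-matter-hyperintensity (WMH)
segmentation** in brain MRI, for researchers who need the non-deep-learning
scaffolding around a lesion-segmentation experiment to be correct, tested
and reproducible: intensity standardization across scanners, adaptive
candidate-lesion detection, blockwise-DCT image fusion, swarm-optimized
parameter tuning, and the full evaluation battery used in WMH challenge
papers — all exercisable end-to-end on synthetic brain phantoms, with no
external data.

## What it computes

**Intensity standardization.** From per-tissue-class statistics
(mean μ_C, population SD σ_C, class maximum, intensity histogram) a
piecewise linear stretch maps the diagnostically relevant range onto
[1, 255]:

    μ_T' = N_PDF − N_max^B + μ_T      P_min = μ_T' − 3σ_T
    μ_V' = N_PDF − N_max^B + μ_V      P_max = μ_V' + 3σ_V

followed by cubic median filtering, optional Gaussian smoothing, and
z-score + min–max normalization to [0, 1].

**Candidate detection.** Voxels above the adaptive threshold
`T = μ_B + k·σ_B` inside the brain mask, refined by morphological opening
with a ball element — speckle and thin vessels vanish, lesion bodies stay.

**PSO tuning.** An inertia-weighted particle swarm
(`v' = θv + α·ε₁(g* − x) + β·ε₂(x* − x)`) minimizes the (optionally
distance-weighted) Dice loss of the thresholded-and-opened mask against a
reference, returning a fitted segmenter object with the standard
`coef`/`predict`/`summary`/`plot` methods.

**Fusion and super-resolution.** 8×8 blockwise orthonormal DCT fusion that
keeps, per block position, the source with more high-band AC energy
(zigzag indices 32–63 vs 1–31), smoothed by a 3×3 consistency vote; plus a
variance-gated, PSO-trained three-block super-resolution mapping for image
patches.

**Evaluation.** Dice loss (plain and weighted by a distance-decaying map
that scores 2 on definite WMH), DSC, HD95, precision/recall/F1 (voxel and
lesion level), average volume difference, PSNR, MSE, SSIM and the
Universal Quality Index, with explicit undefined-metric flags.

## Worked example

```r
library(wmhkit)

ph  <- make_phantom(phantom_config(seed = 1))   # 64 x 64 x 48 phantom
ph
#> <wmh_phantom> 64 x 64 x 48 voxels
#>   voxels per class: background=136480, brain=56764, vessel=102,
#>                     suspected=1250, definite=2012
#>   true lesion volume: 2012.0 mm^3

fit <- wmh_segmenter(ph$volume, brain_mask_of(ph), ph$truth_masks$definite,
                     swarm = swarm_config(n_particles = 15, max_iter = 25,
                                          seed = 1,
                                          bounds = rbind(c(0.5, 1), c(4, 2))))
fit
#> PSO-tuned WMH segmenter
#>   k = 3.4349, structuring radius = 2
#>   Dice loss 0.0352 (DSC 0.9648) after 24 iterations

metric_report(predict(fit), ph$truth_masks$definite,
              spacing = ph$volume$spacing)
#> <wmh_metric_report>
#>   dice_loss  0.03522
#>   dsc        0.9648
#>   hd95       1
#>   precision  0.9699
#>   recall     0.9597
#>   f1         0.9648
#>   avd        1.044
#>   ...
```

The fitted threshold multiplier `k = 3.43` says lesion candidates sit
about 3.4 brain-mask standard deviations above the brain mean on this
phantom; opening radius 2 removed the vessel speckle. On a noisy phantom
with 2012 mm³ of true lesion, the tuned pipeline recovers the lesion mask
at DSC 0.96 with a 1 mm HD95 and a 1 % volume error.

An end-to-end run (phantom → preprocess → tune → evaluate, every
intermediate written as NIfTI plus a checksummed manifest):

```r
run_pipeline(list(seed = 5, out_dir = "out"))
```

or from a shell, via the thin CLI:

```sh
inst/cli/wmhkit run --seed 5 --out out/
inst/cli/wmhkit evaluate --pred out/segmented.nii.gz \
                         --truth out/phantom/labels.nii.gz --out report/
```

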