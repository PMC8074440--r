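# cmrpipe

Fully automatic analysis of multi-sequence cardiovascular MR (CMR) studies
in R. A one-hour CMR exam yields several sequences — cine short-axis for
function, late gadolinium enhancement (LGE) for scar, native and
post-contrast T1 and T2 maps for tissue characterization, and aortic
phase-contrast imaging for flow — and turning them into numbers by hand is
slow and observer-dependent. `cmrpipe` automates the whole chain for each
sequence kind:

1. **Pre-processing** — every 2D slice is resampled to a fixed network grid
   (212 × 212 px at 1.37 × 1.37 mm) with z-scored intensity.
2. **Segmentation** — a sequence-specific 2D U-Net (encoder/decoder with
   skip connections; Adam, lr 0.01, β₁ = 0.9, β₂ = 0.999, batch 5; weighted
   cross-entropy for cine, foreground soft Dice for all other kinds) emits
   per-pixel class probabilities. The network — im2col convolutions,
   pooling, transposed-conv upsampling, batch-norm, backprop — is
   implemented in the package (C++ kernels + R training loop) and verified
   by numerical gradient checks.
3. **Post-processing** — argmax, inverse resampling, 3D stacking, largest
   connected component per structure, per-slice convex hulls
   (cavity := hull(cavity), myocardium := hull(cavity ∪ myo) − hull(cavity)),
   and a random-forest rejector (6 trees, depth 6; features: mean myocardial
   softmax, mean myocardial intensity, normalized slice position) that
   discards over-segmented basal/apical slices of LGE and map stacks.
4. **Parameter extraction** — LV/RV end-diastolic and end-systolic volumes,
   stroke volume, ejection fraction `EF = 100·(EDV − ESV)/EDV`, LV mass
   (1.05 g/mL at ED), scar percentage `100·scar/(myo + scar)` (with
   semi-automatic Otsu scar extraction), mean myocardial T1/T2, and
   net/backward aortic flow `Σ_f Σ_px v·a·Δt`.
5. **Study reporting** — batch processing over a CSV manifest with
   physiological-range outlier flags and Pearson / mean-error /
   Bland–Altman confidence statistics against corrected analyses.

Evaluation uses 3D Dice, Hausdorff distance and mean surface distance
computed on boundary voxels in physical millimetres.

Since no patient data ships with the package, a **synthetic cardiac
phantom** generator produces multi-sequence stacks with exact ground truth
(stacked-disk LV, crescent RV, wedge scar, parabolic aortic velocity
profile) so that training, post-processing, quantification and statistics
are all testable end to end. See the methods vignette
(`vignettes/cmrpipe-methods.Rmd`) for the model, its assumptions and the
design decisions.

## Worked example

```r
library(cmrpipe)

# a synthetic cine study with known ground truth
spec <- phantom_spec("cine", seed = 42)
ph <- make_phantom(spec)
ph$image
#> <cmr_stack> kind=cine dims=[64x64x10x12] spacing=1.37x1.37 mm, slice 10 mm, frame 66.7 ms

# clinical parameters from the ground-truth segmentation
extract_params(ph$truth$mask)
#> <cardiac_params> kind=cine
#>   ed_frame: 1
#>   es_frame: 7
#>   lv_edv_ml: 35.66
#>   lv_esv_ml: 15.17
#>   lv_sv_ml: 20.5
#>   lv_ef_pct: 57.47
#>   lv_mass_g: 42.17
#>   rv_edv_ml: 29.32
#>   rv_esv_ml: 15.5
#>   rv_sv_ml: 13.81
#>   rv_ef_pct: 47.12

# agreement between two EF measurement series (absolute-difference rule,
# Bland-Altman limits = bias +/- 1.96 SD)
agreement(c(60, 40, 70, 55), c(58, 44, 69, 51), "percentage")
#>   pearson_r mean_error bias   loa_low loa_high n
#> 1 0.9692234       2.75 0.75 -5.920722 7.420722 4
```

The phantom's end-diastolic frame is frame 1 and end-systole falls
mid-cycle (frame 7); the EF of 57.5% is recovered exactly from the
voxel-counted cavity volumes, which is the self-consistency anchor the
whole parameter layer is tested against. Training a model and segmenting a
stack follows the same API:

```r
ts <- make_training_slices("t2", 200, seed = 1)
model <- unet_build(unet_config("t2", input_shape = c(64L, 64L)), seed = 1)
model <- train_unet(model, ts$images, ts$masks, train_config("t2", max_epochs = 6))
rejector <- train_rejector_from_model(model, seed = 2)
seg <- segment_stack(model, ph_t2$image, rejector = rejector)
evaluate_masks(seg$mask, ph_t2$truth$mask)   # per-structure Dice / HD / MSD
```

A command-line interface wraps the same functions
(`inst/exec/cmrpipe phantom|train|segment|analyze|evaluate|report`).

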