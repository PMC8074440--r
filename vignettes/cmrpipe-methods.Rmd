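---
title: "Methods: automatic multi-sequence CMR segmentation and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic multi-sequence CMR segmentation and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`cmrpipe` implements a fully automatic analysis pipeline for multi-sequence
cardiovascular MR (CMR) studies. A study contributes up to six sequence
kinds — cine short-axis, late gadolinium enhancement (LGE), native and
post-contrast T1 maps, T2 maps, and aortic phase-contrast flow — and the
pipeline processes each with the same five stages:

1. **Pre-processing**: every 2D slice is resampled to a fixed network grid
   (212 × 212 pixels at 1.37 × 1.37 mm by default) and intensity-normalized.
2. **Segmentation**: a sequence-specific 2D U-Net emits a per-pixel softmax
   over that kind's anatomical classes (cine: background / LV cavity / LV
   myocardium / RV cavity; LGE: background / LV cavity / myocardium / scar;
   maps: background / LV cavity / myocardium; flow: background / aorta).
3. **Post-processing**: per-pixel argmax, inverse resampling and stacking to
   the acquisition grid, largest-connected-component filtering, per-slice
   convex-hull regularization, and — for LGE and map stacks — random-forest
   rejection of over-segmented basal/apical slices.
4. **Parameter extraction**: ventricular volumes, ejection fractions, LV
   mass, scar percentage, mean myocardial relaxation times, and net/backward
   aortic flow.
5. **Study reporting**: batch processing over a manifest, with
   physiological-range outlier flags and optional confidence statistics
   against corrected analyses.

Because no patient data ships with the package, a synthetic cardiac phantom
generator with analytically known ground truth drives development, testing
and the acceptance experiments end to end.

# The phantom generator

The phantom emulates the topology of short-axis CMR, not its MR physics.
Per slice the left ventricle is a cavity disk inside a myocardial annulus;
radii taper linearly toward the apex. The right ventricle (cine only) is a
crescent: a laterally displaced disk minus the epicardial disk. LGE scar is
an angular wedge strictly inside the myocardium, parameterized by angular
extent and transmurality. The aorta (flow) is a disk carrying a parabolic
through-plane velocity profile `v(r) = v_peak (1 − (r/R)²)` modulated in
time by `0.9 sin(2πf/n) + 0.35`, so late-cycle frames are net-negative and
backward flow is nonzero.

A voxel belongs to a structure iff its center lies inside the analytic
shape, so ground-truth volumes are exact voxel counts; every derived truth
(EF, scar fraction, map means, flow integrals) is computed from the
voxelized mask, making parameter recovery testable to numerical precision.
Images are per-label tissue means plus Gaussian noise; all output is a pure
function of the spec (including its seed).

Reference study conditions, fixed once: 64 × 64 grid at 1.37 mm (0.78 mm
for flow, a typical phase-contrast resolution), 10 slices with the heart on
slices 3–9, 8 mm structural / 10 mm cine slice thickness, an 800 ms cardiac
cycle with 12 cine / 20 flow frames, and per-kind tissue means in plausible
units (e.g. native T1: myocardium 1000 ms, blood 1600 ms; LGE: background
40, myocardium 60, scar 130, blood 140 arbitrary units). The LGE values are
deliberately low-contrast between normal myocardium and background — on
real LGE both are dark — which makes LGE the hardest kind here, as it is in
practice. Static-kind phantoms additionally carry a faint non-cardiac
"ghost" disk on the slice just basal of the heart: the out-of-ventricle
tissue that 2D models over-segment and that the slice rejector exists to
remove. Population variability for training is emulated by jittering
geometry (radii, wall thickness, taper, center), tissue means (± 8%) and
scar morphology across phantoms.

What the phantom does **not** emulate: coil bias fields, k-space artifacts,
papillary muscles and trabeculation, through-plane motion, partial-volume
averaging beyond voxel-center membership, and anatomically realistic RV
inflow/outflow. Passing the phantom experiments therefore demonstrates that
the pipeline's machinery — learning, geometry, rejection, quantification —
is correct and self-consistent at desk scale, not that the shipped
configuration meets clinical accuracy on scanner data; the models are meant
to be retrained on real cohorts.

# Pre-processing choices

Slices are bilinearly resampled to the target pixel spacing, z-scored, and
center-cropped / zero-padded to the target shape; label maps travel the
inverse path with nearest-neighbor resampling, so they never acquire labels
outside their input set. Records of each transform make the spatial mapping
invertible.

Normalization uses **stack-level** mean/SD when a whole stack is processed
(`preprocess_stack()`), not per-slice statistics. Per-slice z-scoring maps
an empty, noise-only slice to unit-variance noise — indistinguishable in
scale from tissue texture — and we observed 2D models hallucinating cardiac
structure on such slices. With stack statistics an empty slice stays flat
and far from tissue intensity, and the hallucination disappears. A single
slice normalized in isolation (`to_network_grid()` default) still uses its
own statistics, which keeps the documented affine-invariance property
`z(ax + b) = z(x)`.

# Segmentation models

Each sequence kind has an independent 2D U-Net: a symmetric encoder of 3 × 3
convolution + batch-norm + ReLU blocks with 2 × 2 max-pooling, a decoder
with 2 × 2 transposed-convolution upsampling and skip connections at every
resolution, and a 1 × 1 output convolution. Default depth is 4 resolution
levels starting at 16 channels (doubling per level); inputs are internally
zero-padded to a multiple of `2^(depth−1)` and the logits cropped back, so
the output mask always matches the input resolution (212 is not divisible
by 8; padding is the standard resolution-preserving remedy). Normalization
layers use batch statistics in training and inference alike — with a single
image this is instance normalization — keeping prediction a deterministic
function of weights and input.

Training uses Adam (learning rate 0.01, β₁ = 0.9, β₂ = 0.999) with batch
size 5 and no schedule. The loss is fixed by kind: cine minimizes a
weighted cross-entropy; all other kinds maximize foreground soft Dice,
`(2Σpt + ε) / (Σp + Σt + ε)` averaged over non-background classes with
ε = 10⁻⁵ in numerator and denominator so absent structures with near-zero
predictions score 1 rather than being penalized. Cine class weights are
inverse pixel frequencies renormalized to mean 1 and clipped to
`[0.25, 4]`: unclipped, the abundant background class costs so little to
ignore (weight ≈ 0.07) that the model hallucinates foreground on empty
slices.

The whole network — im2col convolutions backed by BLAS, pooling, transposed
convolutions, batch-norm — is implemented in this package (C++ kernels, R
training loop) and verified by numerical gradient checks agreeing with
analytic gradients to ~10⁻¹⁰ relative error, and by the overfit-one-batch
property (loss < 0.05 within 200 steps on a single slice), which catches
broken gradient paths.

Desk-scale training protocol: 200 phantom slices per kind, per-kind epoch
budgets of 10 (cine), 16 (LGE) and 6 (maps, flow), set from loss-convergence
behavior — LGE's low myocardium/background contrast converges markedly
slower; the others plateau within a few epochs. Empty (background-only)
slices are all kept: deciding that a basal or apical slice contains no
ventricle is half the segmentation problem, and models trained with few
empty examples hallucinate myocardial rings on noise-only slices of unseen
subjects. At most 8 slices are drawn per phantom — a cine stack alone
offers 120 slice/frame pairs, and without the cap a 200-slice set would
represent only two subjects; with it, the budget spans roughly 25 phantoms
and the between-subject variation that matters for generalization.

# Post-processing

The order is fixed: argmax (ties to the lowest class index) → inverse
resampling and stacking → largest connected component per structure
(26-connectivity in 3D; the aorta per frame with 8-connectivity in-plane;
ties keep the component whose minimal (slice, row, col) index is smallest)
→ per-slice convex hulls → slice rejection. Each step is idempotent on its
own output.

"Convexity of the myocardium" is realized as convex endo- and epicardial
contours: the cavity becomes the hull of its pixels, the epicardial region
the hull of cavity ∪ myocardium, and the myocardium their difference — an
annulus is not itself convex, and 3D hulls would bridge base and apex, so
hulls are strictly per 2D slice. Scar is exempt from both hulling and
component filtering (it is legitimately fragmented) but is clipped to the
final myocardial ring; the RV is left unhulled and restored only where the
LV hulls did not claim pixels.

## The slice rejector

2D models over-segment around the basal and apical extent of the ventricle
— an extra slice that resembles myocardium locally but that a human, seeing
the stack, would not segment. A random forest (6 trees, maximum depth 6,
majority vote) classifies each segmented slice as keep/discard from three
features: the mean softmax of the predicted myocardium, the mean normalized
image intensity over those pixels, and the normalized slice position
`(i − 1)/(n − 1)` with slice 1 most basal. Labels for training come from
comparing model output with ground truth: a slice the model segments that
is empty in the truth is a discard example. Slices with no predicted
myocardium are discarded without consulting the forest (their features are
undefined). Rejection applies to LGE and map stacks only — cine and flow
stacks refuse it.

The rejector is trained either from a model's own predictions on phantoms
(`train_rejector_from_model()`, 30 phantoms by default — enough that the
forest sees the between-subject spread of the intensity feature rather than
memorizing one cohort's intensity level) or from the synthetic
over-segmentation corpus (`make_rejection_corpus()`), where emulated softmax
maps are confident on true slices and less confident on the over-segmented
ghost tissue.

# Parameters

Volumes are voxel sums (`count × voxel volume`); slice summation is
Simpson's rule at slice resolution. ED/ES are the frames of maximal/minimal
LV-cavity volume (ties → earliest). EF is `100 (EDV − ESV)/EDV`, clamped to
0 with a warning if segmentation error makes ESV exceed EDV, so the
invariant `0 ≤ EF ≤ 100` survives bad inputs. LV mass is myocardial volume
at ED times the 1.05 g/mL muscle-density convention. Scar percentage uses
the whole-muscle denominator, `100 · scar/(myocardium + scar)` — scar is
diseased myocardium, so it belongs to the mass it is a percentage of. Map
means average raw milliseconds over myocardium voxels across all slices.
Flow integrates `Σ v·a` per frame times the frame duration, with positive
velocity antegrade; backward flow is the magnitude of the summed negative
per-frame contributions. Otsu scar extraction maximizes between-class
variance on a 256-bin histogram of within-myocardium intensities and labels
the bright class scar; it is shift-invariant and refuses constant regions.

# Evaluation metrics

Dice, Hausdorff distance and mean surface distance are computed in 3D.
Boundaries are voxels with at least one face-adjacent non-structure
neighbor (array borders count); distances are between voxel centers in
physical millimetres with anisotropic spacing. Both-empty Dice is defined
as 1 and one-empty as 0; HD/MSD are reported missing when either side is
empty. Temporal stacks aggregate per frame: maximum over frames for HD,
mean for MSD. All three metrics are cross-checked against brute-force
oracles (set arithmetic for Dice; all-pairs max-min / mean-min for the
distances) on randomized small masks.

Parameter agreement follows the percentage/numerical rule: EF and scar
percentage use the mean absolute difference; every other parameter the mean
absolute relative difference (in percent). Bland–Altman summaries report
the bias and `bias ± 1.96 SD` limits of agreement. Pearson correlation is
reported missing when either vector has zero variance.

# Study reporting

`run_study()` processes a manifest row by row, segmenting with per-kind
models (or analyzing stored masks when none is supplied), and never lets
one subject's failure abort the batch — failures are logged rows. A
parameter row is flagged iff it lies outside its inclusive physiological
range; the flag logic is exactly the range predicate. The shipped ranges
(`inst/extdata/physio_ranges.yaml`) are clinical-scale review triggers and
are deliberately per-study configuration: analyses of the desk-scale
phantom population pass their own ranges. `confidence()` compares automatic
and corrected parameter sets with the agreement machinery, the
global-confidence indicator for a cohort.

# Numerical and design notes

* Slice ordering: slice 1 is most basal; normalized position
  `(i − 1)/(n − 1)`. Acquisitions with the opposite ordering must be
  flipped on ingest.
* Frame duration defaults to an 800 ms cycle divided by the frame count
  when the NIfTI header and YAML sidecar are silent.
* Argmax ties break to the lowest class index; equal-size component ties
  keep the lexicographically first component; Otsu plateaus (empty
  histogram gaps) resolve to the first maximizing bin edge — all choices
  exist to make reruns byte-identical.
* Checkpoints are plain-text JSON (flattened weights plus configuration).
* Problem sizes used by the acceptance experiments: 64 × 64 phantoms, 200
  training slices and the per-kind epoch budgets above, 3 held-out stacks
  per kind, a 100-stack rejection corpus split 60/40, and 100 randomized
  mask pairs for the metric oracles. These sizes are the package's
  desk-scale reference experiment; larger studies simply supply more data.

# Known limitations

The phantom's simplicity means segmentation Dice here is far above what
scanner data yields; the pipeline's clinical accuracy is a property of the
training data it is given. The RV basal slice — a known weak point of 2D
models — has no dedicated correction (the rejector covers LV-only kinds).
Uncertainty estimation is out of scope. The convex-hull step assumes
slice-wise convex endo/epicardial contours, which is violated by extreme
shape abnormalities. DICOM ingestion is out of scope; data enter as NIfTI
with a CSV manifest.
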