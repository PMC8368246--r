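---
title: "Quantifying cervical muscle fat infiltration from Dixon MRI"
author: "DixonMFI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cervical muscle fat infiltration from Dixon MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DixonMFI)
```

## The measurement problem

Fat infiltration of the cervical musculature (MFI) is a candidate imaging
biomarker in neck pain, whiplash and degenerative spine disease. Two-point
Dixon MRI acquires the fat and water proton signals in a single sequence:
the in-phase echo is $IP = W + F$ and the out-of-phase echo is
$OOP = W - F$, so fat-only and water-only images follow algebraically as
$F = (IP - OOP)/2$ and $W = (IP + OOP)/2$. Given a segmentation of a
muscle, its fat infiltration is

$$\mathrm{MFI} = \frac{\overline{F}}{\overline{F} + \overline{W}}
  \times 100,$$

a **ratio of regional means**, not a mean of voxelwise fat fractions. The
two differ on heterogeneous regions; the ratio-of-means form is the one
this package computes. Muscle volume is the voxel count times the voxel
volume ($dx\,dy\,dz/1000$ ml); no partial-volume weighting is applied.

Manual multi-muscle segmentation takes hours per scan, which motivates a
3D convolutional segmentation model. This package provides the full
chain — simulation with known ground truth, augmentation, a compact dense
V-Net, quantification, and the evaluation battery — so that every stage
is testable on a desk without any clinical data.

## The label scheme

Seven bilateral muscle groups are segmented with separate left/right
labels 1–14 (background 0), each restricted to predetermined vertebral
levels: MFSS (C4–C6, labels 2/1), LC (C3–C6, 4/3), SSCap (C3–C5, 8/7),
SPCap (C3–C5, 6/5), LS (C5–C6, 14/13), SCM (C4–C6, 10/9) and TR (C6,
12/11). `defaultLabelScheme()` encodes this table. The scheme class also
permits unpaired midline entries (`right = NA`); the desk-scale training
scheme uses one for the vertebral column so that a 4-class problem
(background, left muscle, right muscle, bone) exists at CPU scale.

## The synthetic phantom

`generatePhantom()` builds an axial neck-like section on a configurable
grid (default $64 \times 48 \times 12$ voxels at
$0.7 \times 0.7 \times 3.0$ mm): an elliptical body cross-section filled
with mixed soft tissue (fat fraction 0.35), a subcutaneous fat shell
(0.9), a central vertebral column (fat fraction 0.15 at reduced total
signal), and mirror-symmetric elliptic-cylinder muscle pairs whose axial
extents mimic the per-group vertebral restriction. Default true fat
fractions grade from deep to superficial (MFSS 0.17, LC 0.14, SSCap
0.15, SPCap 0.09, SCM 0.09, TR 0.08, LS 0.07), matching the magnitude
ordering reported for cervical muscles in vivo. Each voxel receives
$F = f\,S$ and $W = (1 - f)S$ plus independent zero-mean Gaussian noise
(default sd 5 on a tissue signal of 100, i.e. SNR 20). Noise is applied
in the fat/water domain so that the Dixon round trip stays exact and the
ratio-of-means estimator remains analyzable; Rician magnitude noise on
the echoes is available as an option. Negative values produced by noisy
decomposition are kept (clipping is opt-in) because clipping would bias
the estimator under zero-mean noise.

What the phantom does **not** emulate: bias fields, chemical-shift and
metal artifacts, fat–water swaps, anatomical shape variability, or
partial-volume mixing at muscle boundaries. Passing tests on phantoms
therefore demonstrates correctness of the algorithms and the estimators'
statistical behaviour, not clinical segmentation performance.

Simulated "imperfect raters" (`perturbMask()`) apply boundary-localized
noise standing in for human interrater variability, in two regimes.
Boundary-voxel flips (each labelled voxel on a label boundary is
reassigned to a random face-neighbour's value with a given rate) emulate
*graded* boundary disagreement: MFI, a ratio of interior means, barely
moves, while volumes drift — which is why the package's reliability
ladder ramps the flip rate and reproduces the characteristic pattern of
MFI reliability exceeding volume reliability under boundary noise.
Whole-label erosion/dilation steps emulate *gross* over/under
segmentation instead; because a single dilated shell mixes a large
fraction of surrounding tissue (fat fraction 0.35) into a muscle region
(0.07–0.17), they degrade MFI and volume together and saturate agreement
statistics in one step rather than progressively. Synthetic
cohorts (`generateCohort()`) draw per-subject bilaterally averaged MFI
from an additive model with a female–male offset (default 1.8%), larger
age slopes in the deep groups (0.07 vs 0.02 %/year, chosen to put the
deep-muscle partial correlations near $r \approx 0.35$ at the default
noise levels), a subject random effect (sd 1.5%) and residual noise
(sd 1.0%); ages and BMI come from truncated normals (34.2 ± 10.7 years
on 18–65; 25.9 ± 4.5 kg/m² on 16–45), and the default cohort is 84
subjects with 61 females, mirroring the study design this toolkit
targets.

## Augmentation

`augmentDataset()` chains, in fixed order, left–right mirroring →
elastic deformation → anisotropic scaling → three-axis rotation, with
independent draws per sample. Defaults: mirror probability 0.5, elastic
deformation with 3 control points per axis and control-point
displacement sd ("sigma") of 10 voxels interpolated trilinearly to the
voxel grid, per-axis scaling of ±2.5%, rotations of ±2.5° about the
left–right and anterior–posterior axes and ±5° about the
superior–inferior axis. Intensities are warped with trilinear
interpolation, label maps with nearest neighbour, and out-of-field
voxels become background.

Two policies deserve emphasis. First, mirroring **swaps each left label
with its paired right label**; without the swap, flipped samples would
teach a network anatomically impossible label–side associations. Second,
sources are consumed in randomized round-robin order, so usage across
source scans is uniform by construction. Histogram standardization
(`fitLandmarks()` / `histogramStandardize()`) maps per-image deciles
onto pooled landmarks with a monotone piecewise-linear transfer, and
`normalizeLabels()` maps scheme labels to contiguous training indices
(the identity for the default 0–14 scheme).

## The dense V-Net

`buildDenseVNet()` constructs a fully convolutional 3D network with the
architectural ingredients of the dense V-Net family: dense feature
stacks at two resolution levels (each dense layer concatenates all
previous features before a 3×3×3 convolution), dilated convolutions
within the blocks, V-Net-style average-pool downsampling and nearest
upsampling with a full-resolution skip concatenated into the head,
batch-wise spatial dropout on the skip features, and a 1×1×1 output
convolution followed by a voxelwise soft-max. Channel widths, block
depths, dilation rates and the pooling factors are configuration, so a
tiny CPU variant exists alongside larger settings. The forward and
backward passes are implemented in C++ within the package; training is
single-threaded and fully deterministic given the seed.

The loss is a **Dice hinge**: per foreground class present in the
target, the soft Dice loss $1 - 2|PT|/(|P|+|T|)$ is computed, classes
whose loss is already below a margin (default 0.1) are clamped to zero,
and the rest are averaged. The clamping limits the gradient share of
already-solved classes (and of the dominant background, which is only
scored when a window contains no foreground at all). Setting the margin
to zero recovers plain soft Dice (`loss = "dice"`).

Training (`trainDenseVNet()`) uses uniform window sampling, Adam
(learning rate 0.001) with $\ell_2$ decay $10^{-5}$, ReLU activations,
and stops when the validation Dice plateaus; following the convention of
validating on the non-augmented raw training volumes, `val_data`
defaults to the training set. Dice-loss training of bilaterally
symmetric targets has a characteristic failure mode: the optimizer can
settle into a left/right label-assignment local optimum where the
soft-max outputs are confidently wrong and the Dice gradient nearly
vanishes. Because the network is initialized with random weights, an
optional restart policy (`restarts`, `restart_dice`) re-initializes and
retrains when the best validation Dice at the plateau is below a
threshold, keeping the best attempt; the acceptance script allows up to
four restarts. The trap is a property of the random initialization and
its early trajectory (not of the training data, the learning rate, or
the receptive field — each was ruled out by controlled reruns), which is
why fresh re-initialization is the appropriate remedy. At full scale the published recipe uses a
360 × 240 × 32 window and batch 3; the desk-scale defaults here are a
48 × 48 × 8 window and batch 2 on 4-class phantoms, which reach held-out
foreground Dice above 0.9 in about 250 iterations on one CPU — the
problem sizes used throughout the tests and the acceptance script.
`preprocessVolume()` handles resampling to the target spacing (trilinear
for intensities, nearest for labels) and symmetric zero padding, and
refuses to crop. The published pad target "90 × 60 × 8" is inconsistent
with that pipeline's own window and is treated as configuration rather
than resolved by guessing.

The network consumes IP/OOP channel pairs rather than fat/water: the
echo magnitudes are immune to the fat–water swap artifact, and both
contrasts carry complementary boundary information.

## Evaluation battery

Per label, one-vs-rest confusion counts yield Dice, Jaccard
($JI = D/(2-D)$), conformity coefficient ($CC = (3D-2)/D$, negative
when $D < 2/3$), TPR, TNR, PPV and the volume ratio VR
(predicted/reference). TNR is computed over the full grid — with a
dominant background this sits near 1.00 by construction. When a label is
empty in both masks the affected metrics are flagged undefined rather
than scored as perfect, and aggregate rows skip flagged entries;
aggregation is mean ± standard error, with the algebraic identities
holding per scan (not after averaging).

Agreement between paired measure series uses the difference direction
*test − reference*: Bland–Altman bias with 95% limits of agreement
(bias ± 1.96 × sample sd), MAE, RMSE, $r^2$, the regression of the
reference on the test measure through the origin (whose slope corrects
proportional bias), and ICC(2,1) — the two-way random-effects,
absolute-agreement, single-measure intraclass correlation computed from
the ANOVA mean squares, with the F-test of zero ICC and the
F-distribution confidence interval. No multiplicity correction is
applied anywhere in the battery; the analyses are exploratory by design.

## Cohort statistics

On per-subject tables of bilaterally averaged MFI (left/right MFI
percentages averaged; when one side is undefined the other is used and
flagged): pairwise paired t-tests between groups; one-way ANCOVA of sex
with age and BMI covariates (sex coded female = 1 so a positive
coefficient means higher female MFI) with marginal means evaluated at
the covariate means; partial Pearson correlations via two-stage
residual regression with $n - q - 2$ degrees of freedom; and a
repeated-measures ANCOVA with muscle group within subjects, sex between,
and mean-centred age and BMI as covariates. The within-subject tests use
the multivariate formulation on orthonormal polynomial contrasts with
univariate (trace) F statistics; sphericity is handled by
Greenhouse–Geisser correction, with epsilon estimated from the
contrast-space residual covariance (the correction type is a package
choice — reported corrected degrees of freedom of the form
$F(4.5,\,361.8)$ are consistent with it, but other corrections exist).
The between-subject sex test is the ANCOVA on subject means, giving
residual degrees of freedom $n - 4$.

## Numerical and design choices

* Coordinates are (x = left→right, y = posterior→anterior,
  z = inferior→superior); NIfTI affines are honoured on I/O.
* Bland–Altman limits use the sample (n−1) standard deviation.
* Zero-denominator metrics, empty labels and non-positive MFI
  denominators are flagged (`NA` + flag), never silently dropped or
  defaulted.
* ICC confidence intervals use $\alpha = 0.05$ by default.
* All generators and the trainer are pure functions of (spec, seed);
  every random draw flows from a single seed per entry point.
* The elastic field uses trilinear interpolation of the control
  lattice; "sigma" is the control-point displacement sd in voxels.
* Ties in the soft-max argmax resolve to the lowest class index.

## Known limitations

The phantom's piecewise-constant tissue model makes segmentation easier
than clinical data; desk-scale Dice values should not be read as
clinical performance. The dense V-Net here is a compact CPU
implementation sharing the family's structural ingredients, not a
layer-for-layer replica of any published configuration. The
repeated-measures ANCOVA matches this package's documented definition;
other software may differ in covariate handling and sphericity
correction. Multi-echo Dixon fitting, $T_2^*$ correction, phase
unwrapping and fat–water swap correction are out of scope.
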