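# DixonMFI

Automated quantification of cervical spine muscle composition from
two-point Dixon fat–water MRI.

Fat infiltration of the neck muscles (MFI) is consistently elevated in
cervical spine disorders — most strongly in the deep muscle layers — but
measuring it requires segmenting up to 14 muscles per scan by hand.
`DixonMFI` implements the complete computational chain around an
automated, CNN-based replacement for that manual step, together with the
simulation machinery needed to validate every stage without clinical
data:

* **Dixon signal algebra** — in-phase/out-of-phase composition and
  decomposition (`IP = W + F`, `OOP = W − F`, `F = (IP − OOP)/2`,
  `W = (IP + OOP)/2`), and per-muscle measures
  `MFI = F̄/(F̄ + W̄) × 100` (ratio of means) and volume in ml.
* **A 14-label bilateral muscle scheme** (MFSS, LC, SSCap, SPCap, LS,
  SCM, TR; separate left/right labels at predetermined vertebral
  levels).
* **A compact 3D dense V-Net** (dense feature stacks, dilated
  convolutions, V-Net down/upsampling with skip forwarding, spatial
  dropout, Dice-hinge loss) with CPU C++ kernels, seeded deterministic
  training, and probabilistic + hard-label inference.
* **Label-aware volumetric augmentation** — left–right mirroring with
  anatomical label swapping, coarse-lattice elastic deformation,
  anisotropic scaling, three-axis rotation, histogram standardization,
  label normalization.
* **Synthetic data with ground truth** — Dixon phantoms of bilaterally
  paired muscles with known fat fractions, simulated imperfect raters,
  and synthetic cohorts with injected sex/age effects.
* **The full evaluation battery** — Dice, Jaccard, conformity
  coefficient, TPR, TNR, PPV, volume ratio; Bland–Altman bias and 95%
  limits of agreement, MAE, RMSE, r², regression through the origin,
  ICC(2,1) with CI and F-test; paired t-tests, sex ANCOVA with marginal
  means, partial correlations, and repeated-measures ANCOVA with
  Greenhouse–Geisser correction.

See the methods vignette (`vignettes/dixonmfi-methods.Rmd`) for the
model, its assumptions, and the design decisions.

## Worked example

Generate a noiseless phantom, measure it, and check the measures against
the built-in truth:

```r
library(DixonMFI)

ph <- generatePhantom(phantomSpec(noise_sd = 0))
m  <- measureAll(ph$volume, ph$mask)
head(m[, c("label", "group", "side", "mfi_percent", "volume_ml")], 4)
#>   label group  side mfi_percent volume_ml
#> 1     1  MFSS right          17   0.47628
#> 2     2  MFSS  left          17   0.47628
#> 3     3    LC right          14   0.56448
#> 4     4    LC  left          14   0.56448
```

MFI equals the specified fat fraction × 100 exactly (the MFSS phantom
muscles were built at fat fraction 0.17), and volume is voxel count ×
voxel volume. Agreement between a ground truth and a simulated imperfect
rater:

```r
mk <- function(i) {           # six phantoms with varying truth
  sp <- phantomSpec(noise_sd = 3, seed = i)
  sp$fat_fractions <- sp$fat_fractions * (0.8 + 0.05 * i)
  sp$geometry$rx <- sp$geometry$rx * (0.65 + 0.05 * i)
  sp$geometry$ry <- sp$geometry$ry * (0.65 + 0.05 * i)
  generatePhantom(sp)
}
gt <- do.call(rbind, lapply(1:6, function(i)
  measureAll(mk(i)$volume, mk(i)$mask, scan_id = paste0("s", i))))
rater <- do.call(rbind, lapply(1:6, function(i) {
  ph <- mk(i)
  pm <- perturbMask(ph$mask, raterPerturbSpec(boundary_shift = 0,
                                              flip_rate = 0.1, seed = i))
  measureAll(ph$volume, pm, scan_id = paste0("s", i))
}))
rel <- reliabilityReport(gt, rater)
rel[rel$label == 2, c("group", "measure", "bias", "mae", "icc21")]
#>   group measure     bias     mae icc21
#> 3  MFSS     MFI -0.01019 0.01893 1.000
#> 4  MFSS  volume -0.00711 0.00711 0.997
```

Resampling 10% of the boundary voxels barely moves MFI (bias ≈ −0.01
percentage points, ICC(2,1) ≈ 1.00): the ratio-of-means estimator is
robust to rater-style boundary noise, while volumes degrade faster as
the noise grows — the pattern the evaluation battery is designed to
expose (see the reliability ladder in `tests/testthat/test-acceptance.R`).

Desk-scale network training on simulated scans (4 classes, 48×48×8
window, one CPU, a few minutes):

```r
phs <- lapply(1:24, function(i) generatePhantom(deskPhantomSpec(seed = i)))
scheme <- deskPhantomSpec()$scheme
samples <- lapply(phs, function(p) makeTrainingSample(p$volume, p$mask, scheme))
model <- trainDenseVNet(buildDenseVNet(denseVNetConfig(n_classes = 4)),
                        samples[1:20],
                        config = trainingConfig(batch_size = 2,
                                                max_iterations = 250))
seg <- segmentDixon(model, inPhase(phs[[21]]$volume),
                    outOfPhase(phs[[21]]$volume),
                    spacing = voxelSpacing(phs[[21]]$volume))
```

A command-line wrapper over the same functions lives at
`inst/cli/dixonmfi.R` (verbs: `simulate`, `train`, `segment`,
`quantify`, `evaluate`, `reliability`, `characterize`, `demo`).

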