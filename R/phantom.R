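## Synthetic Dixon phantoms with known ground truth, simulated imperfect
## raters, and synthetic cohorts. The phantom emulates an axial cervical
## section: an elliptical body cross-section with a subcutaneous fat
## shell, a central vertebral "bone" column, and bilaterally mirrored
## elliptic-cylinder muscle groups restricted to per-group axial slice
## ranges (the analogue of segmenting each muscle only at predetermined
## vertebral levels). Deep groups carry higher true fat fractions than
## superficial ones.

## default bilateral geometry (mm, for 0.7 x 0.7 mm in-plane spacing on a
## 64 x 48 grid): x_off = |offset of the ellipse centre from the
## mid-sagittal plane|, y_cen = anterior-posterior centre, rx/ry = in-plane
## radii, z ranges map the Table-style vertebral restriction onto 12 slices.
.defaultGeometry <- function() {
  data.frame(
    group = c("MFSS", "LC", "SSCap", "SPCap", "LS", "SCM", "TR"),
    x_off = 0.7 * c(7, 6, 6.5, 16, 21, 14, 9.5),
    y_cen = 0.7 * c(31.5, 17.5, 37.5, 36.5, 28, 12, 41.5),
    rx    = 0.7 * c(4, 3.5, 4.2, 4.2, 3.2, 4, 4),
    ry    = 0.7 * c(3, 2.8, 2.2, 2.2, 2.8, 2.6, 1.5),
    z_lo  = c(1L, 1L, 5L, 5L, 1L, 1L, 1L),
    z_hi  = c(9L, 12L, 12L, 12L, 6L, 9L, 4L),
    stringsAsFactors = FALSE)
}

.defaultFractions <- function() {
  c(MFSS = 0.17, LC = 0.14, SSCap = 0.15, SPCap = 0.09, LS = 0.07,
    SCM = 0.09, TR = 0.08)
}

#' Specification of a synthetic Dixon phantom
#'
#' @param grid integer length-3 grid shape (nx, ny, nz).
#' @param spacing voxel spacing in mm; the default matches a 0.7 x 0.7 mm
#'   in-plane, 3.0 mm slice acquisition.
#' @param scheme [MuscleLabelScheme-class] giving the labels to paint.
#' @param geometry data.frame of per-group geometry in mm: columns
#'   `group, x_off, y_cen, rx, ry, z_lo, z_hi`. `x_off` is mirrored about
#'   the mid-sagittal plane to produce the left/right pair; groups with
#'   `right = NA` in the scheme are painted once at the midline.
#' @param fat_fractions named numeric vector of per-group true fat
#'   fractions in \[0, 1\].
#' @param tissue_signal total (fat + water) signal of soft tissue.
#' @param body_fraction fat fraction of unlabelled soft tissue.
#' @param subcut_fraction fat fraction of the subcutaneous fat shell.
#' @param bone_fraction,bone_signal fat fraction and total signal of the
#'   vertebral column compartment.
#' @param bone_radius radius of the central vertebral column in mm.
#' @param paint_bone paint the unlabelled central bone compartment
#'   (default `TRUE`; turned off when the scheme itself labels the
#'   vertebral column, as in [deskPhantomSpec()]).
#' @param noise_sd standard deviation of the additive zero-mean Gaussian
#'   noise applied independently to the fat and water grids (signal
#'   units).
#' @param noise_model `"gaussian"` (default; applied in the fat/water
#'   domain so Dixon round trips stay exact) or `"rician"` (magnitude
#'   noise applied to IP/OOP before decomposition).
#' @param seed integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return a validated `PhantomSpec` list.
#' @seealso [generatePhantom()]
#' @export
phantomSpec <- function(grid = c(64L, 48L, 12L), spacing = c(0.7, 0.7, 3.0),
                        scheme = defaultLabelScheme(),
                        geometry = .defaultGeometry(),
                        fat_fractions = .defaultFractions(),
                        tissue_signal = 100, body_fraction = 0.35,
                        subcut_fraction = 0.9, bone_fraction = 0.15,
                        bone_signal = 60, bone_radius = 2.95,
                        paint_bone = TRUE, noise_sd = 5,
                        noise_model = c("gaussian", "rician"), seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(grid) == 3L, all(grid >= 8),
            length(spacing) == 3L, all(spacing > 0),
            all(fat_fractions >= 0), all(fat_fractions <= 1),
            noise_sd >= 0, tissue_signal > 0, bone_signal > 0)
  g <- schemeGroups(scheme)
  if (!all(g$group %in% geometry$group))
    stop("geometry missing groups: ",
         paste(setdiff(g$group, geometry$group), collapse = ", "),
         call. = FALSE)
  if (!all(g$group %in% names(fat_fractions)))
    stop("fat_fractions missing groups: ",
         paste(setdiff(g$group, names(fat_fractions)), collapse = ", "),
         call. = FALSE)
  structure(list(grid = as.integer(grid), spacing = as.numeric(spacing),
                 scheme = scheme, geometry = geometry,
                 fat_fractions = fat_fractions,
                 tissue_signal = tissue_signal,
                 body_fraction = body_fraction,
                 subcut_fraction = subcut_fraction,
                 bone_fraction = bone_fraction, bone_signal = bone_signal,
                 bone_radius = bone_radius, paint_bone = paint_bone,
                 noise_sd = noise_sd, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Desk-scale phantom specification (4 tissue classes)
#'
#' A reduced setting for CPU-scale network training: a 48 x 48 x 8 grid
#' with one bilateral deep muscle pair (labels 2/1) plus the vertebral
#' column as a midline label (3), i.e. 4 classes including background.
#'
#' @inheritParams phantomSpec
#' @param ... passed on to [phantomSpec()].
#' @return a `PhantomSpec`.
#' @export
deskPhantomSpec <- function(noise_sd = 4, seed = 1L, ...) {
  scheme <- MuscleLabelScheme(data.frame(
    group = c("MFSS", "VB"), left = c(2L, 3L), right = c(1L, NA),
    levels = c("C4-C6", "vertebral column"), stringsAsFactors = FALSE))
  geometry <- data.frame(
    group = c("MFSS", "VB"),
    x_off = 0.7 * c(8, 0), y_cen = 0.7 * c(30, 22),
    rx = 0.7 * c(5.5, 4.5), ry = 0.7 * c(4.5, 4.5),
    z_lo = c(1L, 1L), z_hi = c(8L, 8L), stringsAsFactors = FALSE)
  phantomSpec(grid = c(48L, 48L, 8L), scheme = scheme, geometry = geometry,
              fat_fractions = c(MFSS = 0.2, VB = 0.5),
              paint_bone = FALSE, noise_sd = noise_sd, seed = seed, ...)
}

## paint an elliptic cylinder; error if it would overwrite anything that
## is not plain body tissue (compartment code 1)
.paintCylinder <- function(comp, xc, yc, rx, ry, zlo, zhi, code) {
  d <- dim(comp)
  x <- seq_len(d[1]); y <- seq_len(d[2])
  inside <- outer(((x - xc) / rx)^2, ((y - yc) / ry)^2, "+") <= 1
  if (!any(inside)) stop("degenerate geometry: empty region", call. = FALSE)
  for (z in zlo:zhi) {
    sl <- comp[, , z]
    hit <- inside & sl != 1L
    if (any(hit))
      stop(sprintf(
        "overlapping geometry: region code %d collides with code %d",
        code, sl[hit][1]), call. = FALSE)
    sl[inside] <- code
    comp[, , z] <- sl
  }
  comp
}

#' Generate a synthetic Dixon phantom with ground truth
#'
#' Builds the compartment map (background, body tissue, subcutaneous fat
#' shell, vertebral column, bilaterally mirrored muscles), assigns each
#' voxel `fat = fraction * S` and `water = (1 - fraction) * S`, and adds
#' zero-mean Gaussian noise of sd `noise_sd` independently to the fat and
#' water grids. Deterministic given the spec (same spec, bit-identical
#' output). Overlapping muscle geometry is rejected with an error.
#'
#' @param spec a [phantomSpec()].
#' @return list with `volume` ([DixonVolume-class]), `mask`
#'   ([SegmentationMask-class]), and `truth`, a data.frame of per-label
#'   `label, group, side, fat_fraction, voxel_count, volume_ml` exact for
#'   the noiseless construction.
#' @examples
#' ph <- generatePhantom(phantomSpec(noise_sd = 0))
#' m <- measureAll(ph$volume, ph$mask)
#' all.equal(m$mfi_percent, 100 * ph$truth$fat_fraction)
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$grid; dx <- spec$spacing
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  xmid <- (nx + 1) / 2
  ## compartment codes: 0 background, 1 body tissue, 2 subcut fat shell,
  ## 3 bone; muscles get 100 + label
  comp <- array(0L, d)
  ## body ellipse sized relative to the grid, shell at radial scale >= .93
  bx <- 0.47 * nx; by <- 0.48 * ny; ycen <- (ny + 1) / 2
  x <- seq_len(nx); y <- seq_len(ny)
  r2 <- outer(((x - xmid) / bx)^2, ((y - ycen) / by)^2, "+")
  body <- r2 <= 1
  shell <- body & r2 > 0.93^2
  for (z in seq_len(nz)) {
    sl <- comp[, , z]
    sl[body] <- 1L
    sl[shell] <- 2L
    comp[, , z] <- sl
  }
  ## vertebral column: central cylinder (bone), full z extent
  if (spec$paint_bone)
    comp <- .paintCylinder(comp, xmid, ycen, spec$bone_radius / dx[1],
                           spec$bone_radius / dx[2], 1L, nz, 3L)
  ## muscles
  g <- schemeGroups(spec$scheme)
  geo <- spec$geometry[match(g$group, spec$geometry$group), ]
  mask <- array(0L, d)
  for (i in seq_len(nrow(g))) {
    xoff <- geo$x_off[i] / dx[1]
    yc <- geo$y_cen[i] / dx[2]
    rx <- geo$rx[i] / dx[1]; ry <- geo$ry[i] / dx[2]
    zlo <- max(1L, geo$z_lo[i]); zhi <- min(nz, geo$z_hi[i])
    sides <- if (is.na(g$right[i])) {
      list(c(xmid, g$left[i]))
    } else {
      list(c(xmid - xoff, g$left[i]), c(xmid + xoff, g$right[i]))
    }
    for (s in sides) {
      comp <- .paintCylinder(comp, s[1], yc, rx, ry, zlo, zhi,
                             100L + s[2])
      mask[comp == 100L + s[2]] <- s[2]
    }
  }
  ## per-voxel noiseless fat fraction and total signal
  frac <- array(0, d); sig <- array(0, d)
  sig[comp == 1L] <- spec$tissue_signal
  frac[comp == 1L] <- spec$body_fraction
  sig[comp == 2L] <- spec$tissue_signal
  frac[comp == 2L] <- spec$subcut_fraction
  sig[comp == 3L] <- spec$bone_signal
  frac[comp == 3L] <- spec$bone_fraction
  for (i in seq_len(nrow(g))) {
    fr <- spec$fat_fractions[[g$group[i]]]
    labs <- c(g$left[i], if (!is.na(g$right[i])) g$right[i])
    for (lab in labs) {
      sel <- comp == 100L + lab
      sig[sel] <- spec$tissue_signal
      frac[sel] <- fr
    }
  }
  fat <- frac * sig
  water <- (1 - frac) * sig
  if (spec$noise_sd > 0) {
    .withSeed(spec$seed, {
      if (spec$noise_model == "gaussian") {
        fat <- fat + array(rnorm(length(fat), 0, spec$noise_sd), d)
        water <- water + array(rnorm(length(water), 0, spec$noise_sd), d)
      } else {
        ## Rician: magnitude noise on the IP/OOP echoes, then decompose
        ip <- sqrt((fat + water +
                      array(rnorm(length(fat), 0, spec$noise_sd), d))^2 +
                     array(rnorm(length(fat), 0, spec$noise_sd), d)^2)
        oop <- sqrt((water - fat +
                       array(rnorm(length(fat), 0, spec$noise_sd), d))^2 +
                      array(rnorm(length(fat), 0, spec$noise_sd), d)^2)
        dec <- suppressWarnings(decomposeDixon(ip, oop))
        fat <- dec$fat; water <- dec$water
      }
    })
  }
  smask <- SegmentationMask(mask, dx)
  truth <- measureAll(DixonVolume(frac * sig, (1 - frac) * sig, dx), smask,
                      spec$scheme, scan_id = "truth")
  truth <- data.frame(label = truth$label, group = truth$group,
                      side = truth$side,
                      fat_fraction = truth$mfi_percent / 100,
                      voxel_count = truth$voxel_count,
                      volume_ml = truth$volume_ml,
                      stringsAsFactors = FALSE)
  list(volume = DixonVolume(fat, water, dx), mask = smask, truth = truth)
}

#' Specification of a simulated imperfect rater
#'
#' @param boundary_shift integer >= 0; number of one-voxel morphological
#'   steps (6-connected) applied to a label chosen for perturbation.
#' @param morph_prob probability in \[0, 1\] that a label is
#'   eroded/dilated at all.
#' @param morph_mode `"random"` (erode or dilate with equal probability),
#'   `"dilate"`, or `"erode"`.
#' @param flip_rate probability in \[0, 1\] that a boundary voxel is
#'   reassigned to a neighbouring value.
#' @param seed integer seed.
#' @return a `RaterPerturbSpec` list.
#' @export
raterPerturbSpec <- function(boundary_shift = 1L, morph_prob = 0.5,
                             morph_mode = c("random", "dilate", "erode"),
                             flip_rate = 0, seed = 1L) {
  morph_mode <- match.arg(morph_mode)
  stopifnot(boundary_shift >= 0, morph_prob >= 0, morph_prob <= 1,
            flip_rate >= 0, flip_rate <= 1)
  structure(list(boundary_shift = as.integer(boundary_shift),
                 morph_prob = morph_prob, morph_mode = morph_mode,
                 flip_rate = flip_rate, seed = as.integer(seed)),
            class = "RaterPerturbSpec")
}

## shift a 3D array by one voxel along axis (+/-1), zero-filled
.shift3d <- function(a, axis, by) {
  d <- dim(a)
  out <- array(vector(typeof(a), 1), d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  if (by > 0) {
    idx_dst[[axis]] <- (1 + by):d[axis]
    idx_src[[axis]] <- 1:(d[axis] - by)
  } else {
    idx_dst[[axis]] <- 1:(d[axis] + by)
    idx_src[[axis]] <- (1 - by):d[axis]
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

## 6-neighbourhood test: TRUE where any face neighbour satisfies bin
.neighborAny <- function(bin) {
  out <- array(FALSE, dim(bin))
  for (axis in 1:3) for (by in c(-1L, 1L))
    out <- out | .shift3d(bin, axis, by)
  out
}

#' Simulate an imperfect rater by perturbing a mask
#'
#' Applies boundary-localised morphological noise: each label is, with
#' probability `morph_prob`, dilated or eroded by `boundary_shift`
#' one-voxel steps (dilation only claims background voxels; erosion
#' releases boundary voxels to background), and boundary voxels are then
#' flipped to a neighbouring value with probability `flip_rate`. The
#' label set can only shrink, never grow.
#'
#' @param mask a [SegmentationMask-class].
#' @param spec a [raterPerturbSpec()].
#' @return the perturbed [SegmentationMask-class].
#' @export
perturbMask <- function(mask, spec) {
  stopifnot(is(mask, "SegmentationMask"), inherits(spec, "RaterPerturbSpec"))
  lab <- mask@labels
  .withSeed(spec$seed, {
    labs <- setdiff(sort(unique(as.vector(lab))), 0L)
    for (l in labs) {
      if (spec$boundary_shift == 0L) break
      if (runif(1) >= spec$morph_prob) next
      dilate <- switch(spec$morph_mode, dilate = TRUE, erode = FALSE,
                       random = runif(1) < 0.5)
      for (step in seq_len(spec$boundary_shift)) {
        bin <- lab == l
        if (dilate) {
          grow <- .neighborAny(bin) & lab == 0L
          lab[grow] <- l
        } else {
          shed <- bin & .neighborAny(!bin)
          lab[shed] <- 0L
        }
      }
    }
    if (spec$flip_rate > 0) {
      ## boundary voxels: labelled voxels with a differently-valued
      ## face neighbour; flip each with prob flip_rate to a random
      ## face-neighbour's value
      d <- dim(lab)
      differs <- array(FALSE, d)
      for (axis in 1:3) for (by in c(-1L, 1L))
        differs <- differs | (.shift3d(lab, axis, by) != lab)
      cand <- which(differs & lab != 0L)
      flip <- cand[runif(length(cand)) < spec$flip_rate]
      if (length(flip)) {
        nb <- expand.grid(axis = 1:3, by = c(-1L, 1L))
        pick <- sample.int(6L, length(flip), replace = TRUE)
        idx <- arrayInd(flip, d)
        for (j in seq_along(flip)) {
          tgt <- idx[j, ]
          tgt[nb$axis[pick[j]]] <- tgt[nb$axis[pick[j]]] + nb$by[pick[j]]
          if (all(tgt >= 1) && all(tgt <= d))
            lab[idx[j, 1], idx[j, 2], idx[j, 3]] <-
              lab[tgt[1], tgt[2], tgt[3]]
        }
      }
    }
  })
  SegmentationMask(lab, mask@spacing)
}

#' Specification of a synthetic cohort
#'
#' Defines the generative model for per-subject bilaterally averaged MFI:
#' `MFI_gi = baseline_g + sex_effect * I(female_i) + slope_g *
#' (age_i - age_mean) + b_i + e_gi`, truncated to \[0, 100\], with
#' subject random effect `b_i ~ N(0, subject_sd)` and residual
#' `e_gi ~ N(0, residual_sd)`. Deep muscle groups (MFSS, LC, SSCap by
#' default) carry the larger age slope. Ages and BMI are drawn from
#' truncated normals.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param female_prop proportion of females (default 61/84).
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param bmi_mean,bmi_sd,bmi_range BMI distribution (kg/m^2).
#' @param baseline named per-group baseline MFI (%).
#' @param sex_effect female - male MFI difference (%), default 1.8.
#' @param age_slope_deep,age_slope_superficial age slopes (%/year).
#' @param deep_groups character vector of deep group names.
#' @param subject_sd,residual_sd random effect standard deviations (%).
#' @param bmi_slope BMI slope (%/unit), default 0.
#' @param seed integer seed.
#' @return a `CohortSpec` list.
#' @export
cohortSpec <- function(n_subjects = 84L, female_prop = 61 / 84,
                       age_mean = 34.2, age_sd = 10.7,
                       age_range = c(18, 65), bmi_mean = 25.9, bmi_sd = 4.5,
                       bmi_range = c(16, 45),
                       baseline = c(MFSS = 16.6, LC = 13.5, SSCap = 14.7,
                                    SPCap = 9.4, LS = 7.0, SCM = 9.1,
                                    TR = 7.9),
                       sex_effect = 1.8, age_slope_deep = 0.07,
                       age_slope_superficial = 0.02,
                       deep_groups = c("MFSS", "LC", "SSCap"),
                       subject_sd = 1.5, residual_sd = 1.0,
                       bmi_slope = 0, seed = 1L) {
  stopifnot(n_subjects >= 2, female_prop >= 0, female_prop <= 1,
            subject_sd >= 0, residual_sd >= 0, age_sd >= 0, bmi_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 female_prop = female_prop, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 bmi_range = bmi_range, baseline = baseline,
                 sex_effect = sex_effect, age_slope_deep = age_slope_deep,
                 age_slope_superficial = age_slope_superficial,
                 deep_groups = deep_groups, subject_sd = subject_sd,
                 residual_sd = residual_sd, bmi_slope = bmi_slope,
                 seed = as.integer(seed)), class = "CohortSpec")
}

.truncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(plo + runif(n) * (phi - plo))
}

#' Generate a synthetic cohort table
#'
#' @param spec a [cohortSpec()].
#' @return data.frame with columns `subject`, `sex` (`"F"`/`"M"`),
#'   `age`, `bmi`, and one bilaterally averaged MFI column per muscle
#'   group (percent).
#' @examples
#' head(generateCohort(cohortSpec(seed = 7)))
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  .withSeed(spec$seed, {
    n <- spec$n_subjects
    nf <- round(n * spec$female_prop)
    sex <- c(rep("F", nf), rep("M", n - nf))
    age <- .truncnorm(n, spec$age_mean, spec$age_sd, spec$age_range[1],
                      spec$age_range[2])
    bmi <- .truncnorm(n, spec$bmi_mean, spec$bmi_sd, spec$bmi_range[1],
                      spec$bmi_range[2])
    bsub <- rnorm(n, 0, spec$subject_sd)
    out <- data.frame(subject = sprintf("S%03d", seq_len(n)), sex = sex,
                      age = age, bmi = bmi, stringsAsFactors = FALSE)
    for (g in names(spec$baseline)) {
      slope <- if (g %in% spec$deep_groups) spec$age_slope_deep else
        spec$age_slope_superficial
      mfi <- spec$baseline[[g]] + spec$sex_effect * (sex == "F") +
        slope * (age - spec$age_mean) +
        spec$bmi_slope * (bmi - spec$bmi_mean) + bsub +
        rnorm(n, 0, spec$residual_sd)
      out[[g]] <- pmin(pmax(mfi, 0), 100)
    }
    out
  })
}
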