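## Training-set augmentation for volumetric Dixon data: label-aware
## left-right mirroring, coarse-lattice elastic deformation, anisotropic
## scaling and three-axis rotation, plus histogram standardization and
## label normalization. All warps keep the grid shape; intensities are
## resampled trilinearly, label maps with nearest neighbour, and
## out-of-field voxels are filled with 0 (background).

#' Augmentation configuration
#'
#' Defaults follow the conventional volumetric recipe: elastic
#' deformation with 3 control points per axis and displacement sd
#' (sigma) of 10 voxels, anisotropic scaling of +/- 2.5 percent, and
#' rotations of +/- 2.5 degrees about the left-right and
#' anterior-posterior axes and +/- 5 degrees about the
#' superior-inferior axis.
#'
#' @param mirror_prob probability of a left-right flip (with label swap).
#' @param control_points elastic control points per axis (>= 1).
#' @param sigma sd of control-point displacements, in voxels.
#' @param scale_percent per-axis scale drawn in `1 +/- scale_percent/100`.
#' @param rot_lr_deg,rot_ap_deg,rot_si_deg rotation ranges (degrees)
#'   about the left-right, anterior-posterior and superior-inferior axes.
#' @param n_augmented number of augmented samples to generate.
#' @param seed integer seed.
#' @return an `AugmentationConfig` list.
#' @export
augmentationConfig <- function(mirror_prob = 0.5, control_points = 3L,
                               sigma = 10, scale_percent = 2.5,
                               rot_lr_deg = 2.5, rot_ap_deg = 2.5,
                               rot_si_deg = 5.0, n_augmented = 2000L,
                               seed = 1L) {
  stopifnot(mirror_prob >= 0, mirror_prob <= 1, control_points >= 1,
            sigma >= 0, scale_percent >= 0, rot_lr_deg >= 0,
            rot_ap_deg >= 0, rot_si_deg >= 0, n_augmented >= 0)
  structure(list(mirror_prob = mirror_prob,
                 control_points = as.integer(control_points), sigma = sigma,
                 scale_percent = scale_percent, rot_lr_deg = rot_lr_deg,
                 rot_ap_deg = rot_ap_deg, rot_si_deg = rot_si_deg,
                 n_augmented = as.integer(n_augmented),
                 seed = as.integer(seed)), class = "AugmentationConfig")
}

## left<->right label permutation vector for a scheme; midline labels map
## to themselves. Returns f such that f[label + 1] is the mirrored label.
.mirrorLookup <- function(scheme) {
  g <- schemeGroups(scheme)
  labs <- schemeLabels(scheme)
  f <- seq_len(max(labs) + 1L) - 1L
  for (i in seq_len(nrow(g))) {
    if (is.na(g$right[i])) next
    f[g$left[i] + 1L] <- g$right[i]
    f[g$right[i] + 1L] <- g$left[i]
  }
  f
}

#' Left-right mirroring with anatomical label swap
#'
#' Flips all grids along the left-right (first) axis and exchanges each
#' left label with its paired right label so that sidedness stays
#' anatomically correct. Midline (unpaired) scheme labels map to
#' themselves. Applying the operation twice is the identity.
#'
#' @param images list of 3D numeric arrays (e.g. IP and OOP, or fat and
#'   water), all of identical shape.
#' @param mask a [SegmentationMask-class] on the same lattice.
#' @param scheme the [MuscleLabelScheme-class]; a mask label absent from
#'   the scheme is an error.
#' @return list with `images` (mirrored list) and `mask`.
#' @export
mirrorLR <- function(images, mask, scheme = defaultLabelScheme()) {
  stopifnot(is.list(images), is(mask, "SegmentationMask"))
  d <- dim(mask@labels)
  for (im in images) .checkSameShape(im, mask@labels, "image/mask")
  labs <- setdiff(unique(as.vector(mask@labels)), 0L)
  bad <- setdiff(labs, schemeLabels(scheme))
  if (length(bad))
    stop("mask labels not in scheme (cannot mirror): ",
         paste(bad, collapse = ", "), call. = FALSE)
  rev_x <- rev(seq_len(d[1]))
  flip <- function(a) a[rev_x, , , drop = FALSE]
  f <- .mirrorLookup(scheme)
  lab <- flip(mask@labels)
  lab[] <- f[lab + 1L]
  list(images = lapply(images, flip),
       mask = SegmentationMask(lab, mask@spacing))
}

## evaluate a displacement/warp: given per-voxel source coordinates,
## resample images (trilinear) and mask (nearest), zero fill
.warpAll <- function(images, mask, cx, cy, cz) {
  d <- if (!is.null(mask)) dim(mask@labels) else dim(images[[1]])
  dims <- as.integer(d)
  out_imgs <- lapply(images, function(a)
    array(.sampleTrilinear(as.numeric(a), dims, cx, cy, cz, 0), d))
  out_mask <- NULL
  if (!is.null(mask)) {
    lab <- array(as.integer(.sampleNearest(as.numeric(mask@labels), dims,
                                           cx, cy, cz, 0)), d)
    out_mask <- SegmentationMask(lab, mask@spacing)
  }
  list(images = out_imgs, mask = out_mask)
}

## identity voxel coordinates for a grid
.gridCoords <- function(d) {
  list(cx = rep(seq_len(d[1]), times = d[2] * d[3]),
       cy = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
       cz = rep(seq_len(d[3]), each = d[1] * d[2]))
}

#' Elastic deformation on a coarse control-point lattice
#'
#' Draws one displacement per control point and axis from
#' `N(0, sigma)` (voxel units), interpolates the coarse field
#' trilinearly to voxel resolution, and warps: intensities with trilinear
#' interpolation, the label map with nearest neighbour (so the label set
#' can only shrink, never grow).
#'
#' @inheritParams mirrorLR
#' @param control_points control points per axis (>= 1).
#' @param sigma displacement sd in voxels; 0 is the identity.
#' @param seed integer seed.
#' @return list with `images` and `mask`.
#' @export
elasticDeform <- function(images, mask, control_points = 3L, sigma = 10,
                          seed = 1L) {
  stopifnot(control_points >= 1, sigma >= 0)
  d <- dim(mask@labels)
  if (sigma == 0) return(list(images = images, mask = mask))
  cp <- as.integer(control_points)
  co <- .gridCoords(d)
  .withSeed(seed, {
    disp <- lapply(1:3, function(ax)
      array(rnorm(cp^3, 0, sigma), c(cp, cp, cp)))
    ## voxel -> control lattice coordinate (1..cp across each axis)
    toLat <- function(v, n) if (cp == 1L) rep(1, length(v)) else
      1 + (v - 1) * (cp - 1) / (n - 1)
    lx <- toLat(co$cx, d[1]); ly <- toLat(co$cy, d[2])
    lz <- toLat(co$cz, d[3])
    dims_cp <- as.integer(c(cp, cp, cp))
    dx <- .sampleTrilinear(as.numeric(disp[[1]]), dims_cp, lx, ly, lz, 0)
    dy <- .sampleTrilinear(as.numeric(disp[[2]]), dims_cp, lx, ly, lz, 0)
    dz <- .sampleTrilinear(as.numeric(disp[[3]]), dims_cp, lx, ly, lz, 0)
    .warpAll(images, mask, co$cx + dx, co$cy + dy, co$cz + dz)
  })
}

#' Random anisotropic scaling and three-axis rotation
#'
#' Draws independent per-axis scale factors in
#' `[1 - s/100, 1 + s/100]` and rotation angles in the given +/- ranges
#' (degrees) about the left-right, anterior-posterior and
#' superior-inferior axes, composes them into one affine about the
#' volume centre (in physical mm coordinates, so anisotropic voxels
#' rotate correctly), and resamples.
#'
#' @inheritParams mirrorLR
#' @param scale_percent scale range in percent.
#' @param rot_deg numeric length-3: +/- ranges (degrees) for rotations
#'   about the (x, y, z) = (left-right, anterior-posterior,
#'   superior-inferior) axes.
#' @param spacing voxel spacing (mm); defaults to the mask spacing.
#' @param seed integer seed.
#' @return list with `images` and `mask`.
#' @export
randomAffine <- function(images, mask, scale_percent = 2.5,
                         rot_deg = c(2.5, 2.5, 5.0),
                         spacing = voxelSpacing(mask), seed = 1L) {
  stopifnot(scale_percent >= 0, length(rot_deg) == 3, all(rot_deg >= 0))
  .withSeed(seed, {
    s <- 1 + runif(3, -scale_percent, scale_percent) / 100
    ang <- runif(3, -rot_deg, rot_deg) * pi / 180
    applyAffineWarp(images, mask, scales = s, angles_rad = ang,
                    spacing = spacing)
  })
}

## deterministic core of randomAffine (also used by preprocessing tests)
applyAffineWarp <- function(images, mask, scales = c(1, 1, 1),
                            angles_rad = c(0, 0, 0),
                            spacing = voxelSpacing(mask)) {
  d <- dim(mask@labels)
  rx <- angles_rad[1]; ry <- angles_rad[2]; rz <- angles_rad[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% diag(scales)
  Ainv <- solve(A)
  co <- .gridCoords(d)
  ctr <- (d + 1) / 2
  ## physical coords relative to centre, pull back through A^{-1}
  p <- rbind((co$cx - ctr[1]) * spacing[1], (co$cy - ctr[2]) * spacing[2],
             (co$cz - ctr[3]) * spacing[3])
  q <- Ainv %*% p
  .warpAll(images, mask, q[1, ] / spacing[1] + ctr[1],
           q[2, ] / spacing[2] + ctr[2], q[3, ] / spacing[3] + ctr[3])
}

#' Generate an augmented dataset
#'
#' Each augmented sample is produced from one source scan by the chain
#' mirror -> elastic -> scale/rotate with independent random draws.
#' Sources are consumed in randomized round-robin order so usage is
#' near-uniform. Per-sample transform provenance is recorded.
#'
#' @param dataset list of samples, each a list with elements `volume`
#'   (a [DixonVolume-class]) and `mask` (a [SegmentationMask-class]).
#' @param config an [augmentationConfig()].
#' @param scheme the [MuscleLabelScheme-class] used for label swapping.
#' @return list of `config$n_augmented` samples, each with `volume`,
#'   `mask` and `provenance` (source index, mirror flag, draw seeds).
#' @export
augmentDataset <- function(dataset, config = augmentationConfig(),
                           scheme = defaultLabelScheme()) {
  stopifnot(length(dataset) > 0, inherits(config, "AugmentationConfig"))
  n <- config$n_augmented
  if (n == 0L) return(list())
  .withSeed(config$seed, {
    ns <- length(dataset)
    ## randomized round-robin: near-uniform source usage by construction
    order_idx <- unlist(lapply(seq_len(ceiling(n / ns)),
                               function(i) sample.int(ns)))[seq_len(n)]
    lapply(seq_len(n), function(i) {
      src <- dataset[[order_idx[i]]]
      imgs <- list(fat = fatSignal(src$volume),
                   water = waterSignal(src$volume))
      msk <- src$mask
      mirrored <- runif(1) < config$mirror_prob
      if (mirrored) {
        m <- mirrorLR(imgs, msk, scheme)
        imgs <- m$images; msk <- m$mask
      }
      seeds <- sample.int(.Machine$integer.max - 1L, 2L)
      if (config$sigma > 0) {
        e <- elasticDeform(imgs, msk, config$control_points, config$sigma,
                           seed = seeds[1])
        imgs <- e$images; msk <- e$mask
      }
      a <- randomAffine(imgs, msk, config$scale_percent,
                        c(config$rot_lr_deg, config$rot_ap_deg,
                          config$rot_si_deg), seed = seeds[2])
      list(volume = DixonVolume(a$images$fat, a$images$water,
                                voxelSpacing(src$volume)),
           mask = a$mask,
           provenance = list(source = order_idx[i], mirrored = mirrored,
                             elastic_seed = seeds[1],
                             affine_seed = seeds[2]))
    })
  })
}

#' Fit pooled intensity landmarks for histogram standardization
#'
#' Nyul-style: per-image decile landmarks averaged over the images.
#'
#' @param images list of numeric arrays.
#' @param probs quantile probabilities (default deciles 0..1).
#' @return numeric matrix attributes-free vector of pooled landmarks with
#'   attribute `probs`.
#' @export
fitLandmarks <- function(images, probs = seq(0, 1, 0.1)) {
  stopifnot(length(images) > 0)
  q <- vapply(images, function(im)
    stats::quantile(as.numeric(im), probs = probs, names = FALSE),
    numeric(length(probs)))
  structure(rowMeans(q), probs = probs)
}

#' Histogram standardization of one image
#'
#' Maps the image's own quantiles onto the pooled landmarks with a
#' monotone piecewise-linear transfer function (clamped outside the
#' landmark range). A constant image is returned unchanged with a
#' warning.
#'
#' @param image numeric array.
#' @param landmarks output of [fitLandmarks()].
#' @return the standardized array (same shape).
#' @export
histogramStandardize <- function(image, landmarks) {
  probs <- attr(landmarks, "probs")
  src_q <- stats::quantile(as.numeric(image), probs = probs, names = FALSE)
  if (max(src_q) - min(src_q) <= 0) {
    warning("constant image: histogram standardization is the identity",
            call. = FALSE)
    return(image)
  }
  ## collapse duplicated source quantiles, keep mapping monotone
  keep <- !duplicated(src_q)
  x <- src_q[keep]
  y <- vapply(split(as.numeric(landmarks), cumsum(keep)), mean, numeric(1))
  out <- stats::approx(x, y, xout = as.numeric(image), rule = 2)$y
  array(out, dim(image))
}

#' Map scheme labels onto contiguous training indices
#'
#' Background stays 0; scheme labels map to `1..K` in increasing label
#' order. For the default 14-label scheme the mapping is the identity.
#'
#' @param mask a [SegmentationMask-class] whose labels all belong to the
#'   scheme (otherwise an error).
#' @param scheme a [MuscleLabelScheme-class].
#' @return list with `mask` (index-valued [SegmentationMask-class]) and
#'   `lookup`, a data.frame `(index, label)`; the mapping is invertible
#'   via [denormalizeLabels()].
#' @export
normalizeLabels <- function(mask, scheme = defaultLabelScheme()) {
  labs <- schemeLabels(scheme)
  present <- setdiff(unique(as.vector(mask@labels)), 0L)
  bad <- setdiff(present, labs)
  if (length(bad))
    stop("unknown mask labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  f <- rep(NA_integer_, max(labs) + 1L)
  f[1L] <- 0L
  f[labs + 1L] <- seq_along(labs)
  lab <- mask@labels
  lab[] <- f[lab + 1L]
  list(mask = SegmentationMask(lab, mask@spacing),
       lookup = data.frame(index = seq_along(labs), label = labs))
}

#' Invert [normalizeLabels()]
#'
#' @param mask index-valued [SegmentationMask-class].
#' @param lookup the lookup table from [normalizeLabels()].
#' @return label-valued [SegmentationMask-class].
#' @export
denormalizeLabels <- function(mask, lookup) {
  f <- rep(NA_integer_, max(lookup$index) + 1L)
  f[1L] <- 0L
  f[lookup$index + 1L] <- lookup$label
  lab <- mask@labels
  lab[] <- f[lab + 1L]
  SegmentationMask(lab, mask@spacing)
}
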