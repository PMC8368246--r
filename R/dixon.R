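## Dixon signal algebra and per-muscle quantification.
##
## Two-point Dixon: IP = W + F, OOP = W - F, so F = (IP - OOP)/2 and
## W = (IP + OOP)/2. MFI is the ratio-of-means fat fraction within a
## muscle region, expressed as a percentage.

#' Compose in-phase / out-of-phase images from water and fat
#'
#' @param water,fat 3D numeric arrays of equal shape (water-only and
#'   fat-only signal).
#' @return list with elements `ip = water + fat` and `oop = water - fat`.
#' @examples
#' x <- composeDixon(array(3, c(2, 2, 2)), array(1, c(2, 2, 2)))
#' x$ip[1]   # 4
#' x$oop[1]  # 2
#' @export
composeDixon <- function(water, fat) {
  water <- as.array(water); fat <- as.array(fat)
  .checkSameShape(water, fat, "water/fat")
  list(ip = water + fat, oop = water - fat)
}

#' Decompose in-phase / out-of-phase images into fat and water
#'
#' Inverts [composeDixon()]: `fat = (ip - oop)/2`, `water = (ip + oop)/2`.
#' Noise in the echoes can produce negative fat or water estimates; these
#' are kept (not clipped) so that zero-mean noise stays zero-mean, but
#' their count is reported. Set `clip = TRUE` to clamp at zero.
#'
#' @param ip,oop 3D numeric arrays of equal shape.
#' @param clip logical; clamp negative fat/water values at 0 (default
#'   `FALSE`).
#' @return list with `fat`, `water`, and `n_negative`, the number of
#'   negative voxels across both grids before any clipping. A warning is
#'   emitted when `n_negative > 0` and `clip = FALSE`.
#' @export
decomposeDixon <- function(ip, oop, clip = FALSE) {
  ip <- as.array(ip); oop <- as.array(oop)
  .checkSameShape(ip, oop, "ip/oop")
  fat <- (ip - oop) / 2
  water <- (ip + oop) / 2
  n_neg <- sum(fat < 0) + sum(water < 0)
  if (n_neg > 0 && !clip)
    warning(sprintf("decomposition produced %d negative voxel values (kept)",
                    n_neg), call. = FALSE)
  if (clip) {
    fat[fat < 0] <- 0
    water[water < 0] <- 0
  }
  list(fat = fat, water = water, n_negative = n_neg)
}

#' Per-muscle fat infiltration (MFI, %)
#'
#' MFI is the mean fat-only signal within the muscle divided by the sum of
#' the mean fat-only and mean water-only signal within the muscle, times
#' 100 (a ratio of means, not a mean of voxelwise ratios).
#'
#' @param dixon a [DixonVolume-class].
#' @param mask a [SegmentationMask-class] on the same lattice.
#' @param label integer label defining the muscle region.
#' @return MFI in percent, or `NA` (flagged via attribute `flag`) when the
#'   label is empty or the denominator is not positive.
#' @examples
#' v <- DixonVolume(array(20, c(2, 2, 1)), array(60, c(2, 2, 1)))
#' m <- SegmentationMask(array(1L, c(2, 2, 1)))
#' muscleMFI(v, m, 1L)  # 25
#' @export
muscleMFI <- function(dixon, mask, label) {
  stopifnot(is(dixon, "DixonVolume"), is(mask, "SegmentationMask"))
  .checkSameShape(dixon@fat, mask@labels, "volume/mask")
  sel <- mask@labels == label
  n <- sum(sel)
  if (n == 0L)
    return(structure(NA_real_, flag = "empty_label"))
  mf <- mean(dixon@fat[sel])
  mw <- mean(dixon@water[sel])
  if (!is.finite(mf + mw) || (mf + mw) <= 0) {
    warning(sprintf("label %d: non-positive mean signal, MFI undefined",
                    label), call. = FALSE)
    return(structure(NA_real_, flag = "nonpositive_denominator"))
  }
  100 * mf / (mf + mw)
}

#' Muscle volume in millilitres
#'
#' `voxel_count(label) * dx * dy * dz / 1000` with spacing in mm.
#'
#' @param mask a [SegmentationMask-class].
#' @param label integer label.
#' @return volume in ml (0 for an empty label).
#' @export
muscleVolume <- function(mask, label) {
  stopifnot(is(mask, "SegmentationMask"))
  sum(mask@labels == label) * prod(mask@spacing) / 1000
}

#' Measure MFI and volume for every label of a scheme
#'
#' @param dixon a [DixonVolume-class].
#' @param mask a [SegmentationMask-class] on the same lattice.
#' @param scheme a [MuscleLabelScheme-class]; defaults to the 14-label
#'   cervical scheme.
#' @param scan_id identifier recorded in the output rows.
#' @return A `MuscleMeasures` data.frame with one row per scheme label:
#'   `scan_id, label, group, side, mfi_percent, volume_ml, voxel_count,
#'   flag`. Mask labels absent from the scheme trigger a warning and are
#'   excluded.
#' @examples
#' ph <- generatePhantom(phantomSpec(noise_sd = 0))
#' head(measureAll(ph$volume, ph$mask))
#' @export
measureAll <- function(dixon, mask, scheme = defaultLabelScheme(),
                       scan_id = "scan") {
  stopifnot(is(dixon, "DixonVolume"), is(mask, "SegmentationMask"),
            is(scheme, "MuscleLabelScheme"))
  .checkSameShape(dixon@fat, mask@labels, "volume/mask")
  g <- scheme@groups
  present <- setdiff(unique(as.vector(mask@labels)), scheme@background)
  unknown <- setdiff(present, schemeLabels(scheme))
  if (length(unknown))
    warning(sprintf("mask labels not in scheme, excluded: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(g))) {
    sides <- if (is.na(g$right[i])) c(midline = g$left[i]) else
      c(left = g$left[i], right = g$right[i])
    for (s in names(sides)) {
      lab <- sides[[s]]
      n <- sum(mask@labels == lab)
      mfi <- suppressWarnings(muscleMFI(dixon, mask, lab))
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = scan_id, label = lab, group = g$group[i], side = s,
        mfi_percent = as.numeric(mfi),
        volume_ml = muscleVolume(mask, lab),
        voxel_count = n,
        flag = if (is.na(mfi)) attr(mfi, "flag") else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$label), ]
  rownames(out) <- NULL
  out
}

#' Average left and right measures per muscle group
#'
#' Left and right MFI (and volume) are averaged per group. If one side is
#' undefined the defined side is used and the row is flagged; if both are
#' undefined the group is flagged undefined.
#'
#' @param measures a `MuscleMeasures` data.frame from [measureAll()].
#' @param scheme the [MuscleLabelScheme-class] used to produce it.
#' @return data.frame with one row per group: `scan_id, group,
#'   mfi_percent, volume_ml, flag`.
#' @export
averageBilateral <- function(measures, scheme = defaultLabelScheme()) {
  g <- scheme@groups
  rows <- lapply(seq_len(nrow(g)), function(i) {
    sub <- measures[measures$group == g$group[i], , drop = FALSE]
    mfi <- sub$mfi_percent
    vol <- sum(sub$volume_ml)
    ok <- !is.na(mfi)
    if (!any(ok)) {
      flag <- "undefined"; m <- NA_real_
    } else if (all(ok)) {
      flag <- ""; m <- mean(mfi)
    } else {
      flag <- "one_side_undefined"; m <- mean(mfi[ok])
    }
    data.frame(scan_id = sub$scan_id[1], group = g$group[i],
               mfi_percent = m, volume_ml = vol, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
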