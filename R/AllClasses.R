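#' @import methods
#' @importFrom stats rnorm runif sd var cor lm pf pt qf qt qnorm anova
#'   coef resid fitted model.matrix t.test predict rbinom complete.cases
#' @importFrom utils write.csv read.csv head
#' @useDynLib DixonMFI, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' DixonVolume: co-registered fat and water signal grids
#'
#' A two-point Dixon acquisition yields in-phase (IP = W + F) and
#' out-of-phase (OOP = W - F) echoes from which fat-only and water-only
#' images are derived algebraically. `DixonVolume` stores the fat and water
#' grids on a common 3D lattice together with the voxel spacing in mm.
#' The axis convention is (x = left to right, y = posterior to anterior,
#' z = inferior to superior).
#'
#' @slot fat 3D numeric array of fat-only signal (arbitrary units).
#' @slot water 3D numeric array of water-only signal, same shape as `fat`.
#' @slot spacing numeric length-3 voxel edge lengths (dx, dy, dz) in mm.
#'
#' @seealso [composeDixon()], [decomposeDixon()], [muscleMFI()]
#' @export
setClass("DixonVolume",
  representation(fat = "array", water = "array", spacing = "numeric"))

setValidity("DixonVolume", function(object) {
  msg <- character()
  if (length(dim(object@fat)) != 3L)
    msg <- c(msg, "fat must be a 3D array")
  if (!identical(dim(object@fat), dim(object@water)))
    msg <- c(msg, "fat and water must have identical shapes")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (anyNA(object@fat) || anyNA(object@water))
    msg <- c(msg, "fat/water must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct a DixonVolume
#'
#' @param fat,water 3D numeric arrays of equal shape.
#' @param spacing numeric length-3 voxel spacing (dx, dy, dz) in mm.
#' @return A [DixonVolume-class] object.
#' @examples
#' v <- DixonVolume(array(1, c(4, 4, 2)), array(3, c(4, 4, 2)), c(0.7, 0.7, 3))
#' inPhase(v)[1, 1, 1]   # 4
#' @export
DixonVolume <- function(fat, water, spacing = c(1, 1, 1)) {
  new("DixonVolume", fat = as.array(fat), water = as.array(water),
      spacing = as.numeric(spacing))
}

#' SegmentationMask: integer label grid on a voxel lattice
#'
#' Voxel values are 0 (background) or positive integer muscle labels drawn
#' from a [MuscleLabelScheme-class].
#'
#' @slot labels 3D integer array.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @export
setClass("SegmentationMask",
  representation(labels = "array", spacing = "numeric"))

setValidity("SegmentationMask", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (anyNA(object@labels))
    msg <- c(msg, "labels must not contain NA")
  else if (any(object@labels != round(object@labels)) ||
           any(object@labels < 0))
    msg <- c(msg, "labels must be non-negative integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentationMask
#'
#' @param labels 3D array of non-negative integer labels.
#' @param spacing numeric length-3 voxel spacing (dx, dy, dz) in mm.
#' @return A [SegmentationMask-class] object.
#' @export
SegmentationMask <- function(labels, spacing = c(1, 1, 1)) {
  a <- as.array(labels)
  storage.mode(a) <- "integer"
  new("SegmentationMask", labels = a, spacing = as.numeric(spacing))
}

#' MuscleLabelScheme: bilateral muscle labelling convention
#'
#' Maps muscle group names to left/right integer labels and to the axial
#' slice (vertebral level) range over which each group is segmented. The
#' default scheme covers the seven bilateral cervical muscle groups (MFSS,
#' LC, SSCap, SPCap, LS, SCM, TR) with labels 1-14 and background 0.
#' Midline (unpaired) structures may be represented with `right = NA`;
#' the default scheme contains none.
#'
#' @slot groups data.frame with columns `group`, `left`, `right`,
#'   `levels` (character description of the vertebral range).
#' @slot background integer background label (0).
#' @export
setClass("MuscleLabelScheme",
  representation(groups = "data.frame", background = "integer"))

setValidity("MuscleLabelScheme", function(object) {
  g <- object@groups
  msg <- character()
  need <- c("group", "left", "right", "levels")
  if (!all(need %in% names(g)))
    return(sprintf("groups must have columns %s", paste(need, collapse = ", ")))
  labs <- c(g$left, g$right[!is.na(g$right)])
  if (anyNA(g$left) || any(labs <= 0) || any(labs != round(labs)))
    msg <- c(msg, "labels must be positive integers (left never NA)")
  if (anyDuplicated(labs))
    msg <- c(msg, "labels must be distinct")
  paired <- !is.na(g$right)
  if (any(g$left[paired] == g$right[paired]))
    msg <- c(msg, "left and right labels must differ within a group")
  if (anyDuplicated(g$group))
    msg <- c(msg, "group names must be unique")
  if (length(object@background) != 1L || object@background %in% labs)
    msg <- c(msg, "background label must be a single value outside the label set")
  if (length(msg)) msg else TRUE
})

#' Construct a MuscleLabelScheme
#'
#' @param groups data.frame with columns `group` (name), `left`, `right`
#'   (integer labels; `right = NA` marks a midline structure), and
#'   optionally `levels` (vertebral range annotation).
#' @param background background label, default 0.
#' @return A [MuscleLabelScheme-class].
#' @export
MuscleLabelScheme <- function(groups, background = 0L) {
  if (is.null(groups$levels)) groups$levels <- NA_character_
  groups$left <- as.integer(groups$left)
  groups$right <- as.integer(groups$right)
  groups$group <- as.character(groups$group)
  groups$levels <- as.character(groups$levels)
  rownames(groups) <- NULL
  new("MuscleLabelScheme", groups = groups[, c("group", "left", "right",
                                               "levels")],
      background = as.integer(background))
}

#' The default 14-label cervical muscle scheme
#'
#' Seven bilateral muscle groups, each segmented at predetermined cervical
#' vertebral levels, with separate left/right labels:
#' multifidus + semispinalis cervicis (MFSS, C4-C6, 2/1), longus colli +
#' longus capitis (LC, C3-C6, 4/3), semispinalis capitis (SSCap, C3-C5,
#' 8/7), splenius capitis (SPCap, C3-C5, 6/5), levator scapulae (LS,
#' C5-C6, 14/13), sternocleidomastoid (SCM, C4-C6, 10/9) and trapezius
#' (TR, C6, 12/11). Background is 0.
#'
#' @return A [MuscleLabelScheme-class] with 14 labels.
#' @examples
#' schemeLabels(defaultLabelScheme())
#' @export
defaultLabelScheme <- function() {
  MuscleLabelScheme(data.frame(
    group  = c("MFSS", "LC", "SSCap", "SPCap", "LS", "SCM", "TR"),
    left   = c(2L, 4L, 8L, 6L, 14L, 10L, 12L),
    right  = c(1L, 3L, 7L, 5L, 13L, 9L, 11L),
    levels = c("C4-C6", "C3-C6", "C3-C5", "C3-C5", "C5-C6", "C4-C6", "C6"),
    stringsAsFactors = FALSE))
}

## ---- generics & accessors ---------------------------------------------

#' @rdname DixonVolume-class
#' @param object,x a DixonVolume or SegmentationMask
#' @export
setGeneric("fatSignal", function(object) standardGeneric("fatSignal"))
#' @rdname DixonVolume-class
#' @export
setGeneric("waterSignal", function(object) standardGeneric("waterSignal"))
#' @rdname DixonVolume-class
#' @export
setGeneric("inPhase", function(object) standardGeneric("inPhase"))
#' @rdname DixonVolume-class
#' @export
setGeneric("outOfPhase", function(object) standardGeneric("outOfPhase"))
#' Voxel spacing accessor
#' @param object an object with a spacing slot
#' @return numeric length-3 (dx, dy, dz) in mm
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' Label array accessor
#' @param object a SegmentationMask
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))

#' @rdname DixonVolume-class
setMethod("fatSignal", "DixonVolume", function(object) object@fat)
#' @rdname DixonVolume-class
setMethod("waterSignal", "DixonVolume", function(object) object@water)
#' @rdname DixonVolume-class
setMethod("inPhase", "DixonVolume", function(object) object@water + object@fat)
#' @rdname DixonVolume-class
setMethod("outOfPhase", "DixonVolume",
          function(object) object@water - object@fat)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "DixonVolume", function(object) object@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "SegmentationMask", function(object) object@spacing)
#' @rdname labelArray
setMethod("labelArray", "SegmentationMask", function(object) object@labels)

#' @rdname DixonVolume-class
setMethod("dim", "DixonVolume", function(x) dim(x@fat))
#' @rdname SegmentationMask-class
#' @param x a SegmentationMask
setMethod("dim", "SegmentationMask", function(x) dim(x@labels))

#' All labels in a scheme (excluding background)
#' @param scheme a [MuscleLabelScheme-class]
#' @return sorted integer vector of labels
#' @export
schemeLabels <- function(scheme) {
  g <- scheme@groups
  sort(c(g$left, g$right[!is.na(g$right)]))
}

#' Scheme groups table
#' @param scheme a [MuscleLabelScheme-class]
#' @return the data.frame of (group, left, right, levels)
#' @export
schemeGroups <- function(scheme) scheme@groups

setMethod("show", "DixonVolume", function(object) {
  d <- dim(object@fat)
  cat(sprintf("DixonVolume %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  fat   range [%.4g, %.4g]\n", min(object@fat), max(object@fat)))
  cat(sprintf("  water range [%.4g, %.4g]\n", min(object@water),
              max(object@water)))
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@labels)
  labs <- sort(unique(as.vector(object@labels)))
  cat(sprintf("SegmentationMask %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat("  labels present:", paste(labs, collapse = " "), "\n")
})

setMethod("show", "MuscleLabelScheme", function(object) {
  cat(sprintf("MuscleLabelScheme: %d groups, background = %d\n",
              nrow(object@groups), object@background))
  print(object@groups)
})

## internal: consistent shape checks
.checkSameShape <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s have dims (%s) vs (%s)", what,
                 paste(dim(a), collapse = ","),
                 paste(dim(b), collapse = ",")), call. = FALSE)
  invisible(TRUE)
}

## internal: run code with a temporarily seeded RNG, restoring state
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}
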