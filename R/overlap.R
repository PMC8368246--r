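## Segmentation performance metrics between a ground-truth and a
## predicted label map, computed per label in one-vs-rest fashion:
## Dice, Jaccard (JI), conformity coefficient (CC), TPR, TNR, PPV and
## volume ratio (VR). TNR is computed over the full grid, which is why it
## is near 1 in practice (background dominates).

#' Voxelwise confusion counts for one label
#'
#' Binarizes both masks at `label` (one-vs-rest) and counts true/false
#' positives/negatives over the whole grid.
#'
#' @param gt,pred [SegmentationMask-class] objects of identical shape
#'   (ground truth and prediction).
#' @param label integer label treated as positive.
#' @return named numeric vector `c(tp, fp, fn, tn)`.
#' @export
confusionCounts <- function(gt, pred, label) {
  stopifnot(is(gt, "SegmentationMask"), is(pred, "SegmentationMask"))
  .checkSameShape(gt@labels, pred@labels, "gt/pred")
  a <- gt@labels == label
  b <- pred@labels == label
  tp <- sum(a & b)
  fp <- sum(!a & b)
  fn <- sum(a & !b)
  c(tp = tp, fp = fp, fn = fn, tn = length(a) - tp - fp - fn)
}

## metrics from raw counts; undefined denominators -> NA
.metricsFromCounts <- function(tp, fp, fn, tn) {
  div <- function(num, den) if (den > 0) num / den else NA_real_
  dice <- div(2 * tp, 2 * tp + fp + fn)
  c(dice = dice,
    ji   = div(tp, tp + fp + fn),
    cc   = if (!is.na(dice) && dice > 0) (3 * dice - 2) / dice else NA_real_,
    tpr  = div(tp, tp + fn),
    tnr  = div(tn, tn + fp),
    ppv  = div(tp, tp + fp),
    vr   = div(tp + fp, tp + fn))
}

#' Overlap metrics for one label
#'
#' Dice = 2TP/(2TP+FP+FN); JI = TP/(TP+FP+FN); CC = (3 Dice - 2)/Dice
#' (negative when Dice < 2/3); TPR = TP/(TP+FN); TNR = TN/(TN+FP);
#' PPV = TP/(TP+FP); VR = predicted volume / reference volume. Metrics
#' with a zero denominator are `NA`; in particular a label empty in both
#' masks yields `NA` Dice/JI/TPR/PPV rather than a perfect score.
#'
#' @inheritParams confusionCounts
#' @return named numeric vector
#'   `c(dice, ji, cc, tpr, tnr, ppv, vr)`.
#' @examples
#' m <- SegmentationMask(array(c(1L, 1L, 0L, 0L), c(4, 1, 1)))
#' overlapMetrics(m, m, 1L)["dice"]  # 1
#' @export
overlapMetrics <- function(gt, pred, label) {
  cc <- confusionCounts(gt, pred, label)
  .metricsFromCounts(unname(cc["tp"]), unname(cc["fp"]),
                     unname(cc["fn"]), unname(cc["tn"]))
}

#' Per-muscle overlap metrics report
#'
#' One row of [overlapMetrics()] per scheme label plus an aggregate row of
#' mean and standard error across labels (undefined entries skipped).
#'
#' @inheritParams confusionCounts
#' @param scheme a [MuscleLabelScheme-class].
#' @return data.frame with columns `label, group, side, dice, ji, cc, tpr,
#'   tnr, ppv, vr`; the aggregate appears as attributes `mean` and `se`.
#' @export
metricsReport <- function(gt, pred, scheme = defaultLabelScheme()) {
  g <- scheme@groups
  rows <- list()
  for (i in seq_len(nrow(g))) {
    sides <- if (is.na(g$right[i])) c(midline = g$left[i]) else
      c(left = g$left[i], right = g$right[i])
    for (s in names(sides)) {
      met <- overlapMetrics(gt, pred, sides[[s]])
      rows[[length(rows) + 1L]] <- data.frame(
        label = sides[[s]], group = g$group[i], side = s, t(met),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$label), ]
  rownames(out) <- NULL
  mcols <- c("dice", "ji", "cc", "tpr", "tnr", "ppv", "vr")
  attr(out, "mean") <- colMeans(out[mcols], na.rm = TRUE)
  attr(out, "se") <- vapply(out[mcols], function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  }, numeric(1))
  out
}
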