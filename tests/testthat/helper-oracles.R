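# Independent brute-force oracles used across the test files. These are
# deliberately naive (explicit loops and sums) so they share no code
# path with the package implementation.

# voxel-enumeration confusion counts for one label
oracleConfusion <- function(gt_arr, pred_arr, label) {
  tp <- fp <- fn <- tn <- 0L
  for (v in seq_along(gt_arr)) {
    a <- gt_arr[v] == label
    b <- pred_arr[v] == label
    if (a && b) tp <- tp + 1L
    else if (!a && b) fp <- fp + 1L
    else if (a && !b) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracleMetrics <- function(gt_arr, pred_arr, label) {
  cc <- oracleConfusion(gt_arr, pred_arr, label)
  tp <- cc["tp"]; fp <- cc["fp"]; fn <- cc["fn"]; tn <- cc["tn"]
  sdiv <- function(a, b) if (b > 0) a / b else NA_real_
  dice <- sdiv(2 * tp, 2 * tp + fp + fn)
  c(dice = unname(dice),
    ji = unname(sdiv(tp, tp + fp + fn)),
    cc = unname(if (!is.na(dice) && dice > 0) (3 * dice - 2) / dice
                else NA_real_),
    tpr = unname(sdiv(tp, tp + fn)),
    tnr = unname(sdiv(tn, tn + fp)),
    ppv = unname(sdiv(tp, tp + fp)),
    vr = unname(sdiv(tp + fp, tp + fn)))
}

# explicit two-way ANOVA decomposition for ICC(2,1)
oracleICC21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- sum(x) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (sum(x[i, ]) / k - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (sum(x[, j]) / n - grand)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    sse <- sse + (x[i, j] - sum(x[i, ]) / k - sum(x[, j]) / n + grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# two-stage residual regression partial correlation
oraclePartialCorr <- function(x, y, controls) {
  cm <- as.matrix(controls)
  rx <- residuals(lm(x ~ cm))
  ry <- residuals(lm(y ~ cm))
  cor(rx, ry)
}

# random small masks on a grid, a handful of labels
randomMask <- function(d, labels, p_bg = 0.5) {
  vals <- sample(c(0L, labels), prod(d), replace = TRUE,
                 prob = c(p_bg, rep((1 - p_bg) / length(labels),
                                    length(labels))))
  SegmentationMask(array(vals, d))
}

# one shared desk-scale trained model per test session (expensive)
.deskModelCache <- new.env(parent = emptyenv())
getDeskModel <- function() {
  if (!is.null(.deskModelCache$model)) return(.deskModelCache$model)
  phs <- lapply(1:24, function(i) generatePhantom(deskPhantomSpec(seed = 100 + i)))
  scheme <- deskPhantomSpec()$scheme
  samples <- lapply(phs, function(ph)
    makeTrainingSample(ph$volume, ph$mask, scheme))
  net <- buildDenseVNet(denseVNetConfig(n_classes = 4), seed = 1)
  tc <- trainingConfig(batch_size = 2L, max_iterations = 250L,
                       eval_every = 25L, patience = 10L, seed = 42L)
  model <- trainDenseVNet(net, samples[1:20], val_data = samples[1:4],
                          config = tc)
  .deskModelCache$model <- list(model = model, phantoms = phs,
                                samples = samples, scheme = scheme)
  .deskModelCache$model
}
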