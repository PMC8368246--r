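## Accuracy / reliability battery for paired measure series:
## Bland-Altman bias and 95% limits of agreement, MAE, RMSE, r-squared,
## regression through the origin, and ICC(2,1) (two-way random effects,
## absolute agreement, single measure) with F-test and confidence
## interval.

#' Bland-Altman statistics for a paired series
#'
#' Differences are taken as `test - reference` (e.g. CNN - GT). Limits of
#' agreement are `bias +/- 1.96 * sd(d)` with the sample (n-1) standard
#' deviation.
#'
#' @param reference,test numeric vectors of equal length (>= 2), one pair
#'   per scan.
#' @return named numeric vector
#'   `c(bias, loa_low, loa_high, mae, rmse, n)`.
#' @examples
#' blandAltman(c(1, 2, 3), c(2, 2, 5))
#' @export
blandAltman <- function(reference, test) {
  if (length(reference) != length(test))
    stop("reference and test must have equal length", call. = FALSE)
  if (length(reference) < 2)
    stop("need at least 2 pairs", call. = FALSE)
  d <- test - reference
  bias <- mean(d)
  s <- stats::sd(d)
  c(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    mae = mean(abs(d)), rmse = sqrt(mean(d^2)), n = length(d))
}

#' Squared correlation and regression through the origin
#'
#' `r2` is the squared Pearson correlation of the pairs. `beta_origin` is
#' the least-squares slope of the reference regressed on the test measure
#' with intercept fixed at 0, `sum(test * reference) / sum(test^2)`, so
#' that `reference ~ beta * test` can be used to correct the test
#' measure's proportional bias.
#'
#' @inheritParams blandAltman
#' @return named numeric vector `c(r2, beta_origin)`; `r2` is `NA` when
#'   either series has zero variance.
#' @export
accuracySummary <- function(reference, test) {
  if (length(reference) != length(test))
    stop("reference and test must have equal length", call. = FALSE)
  if (length(reference) < 2)
    stop("need at least 2 pairs", call. = FALSE)
  r2 <- if (stats::var(reference) > 0 && stats::var(test) > 0)
    stats::cor(reference, test)^2 else NA_real_
  beta <- if (sum(test^2) > 0) sum(test * reference) / sum(test^2) else
    NA_real_
  c(r2 = r2, beta_origin = beta)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Computed from the two-way ANOVA mean squares (subjects = rows,
#' raters = columns): `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)`.
#' The confidence interval follows the F-distribution method of
#' McGraw and Wong; the p value is from `F = MSR/MSE` with
#' `(n-1, (n-1)(k-1))` degrees of freedom (test of ICC = 0).
#'
#' @param values numeric matrix or data.frame, `n` subjects by `k`
#'   raters, complete (no `NA`).
#' @param alpha confidence level is `1 - alpha` (default 0.05).
#' @return list with `icc`, `ci_low`, `ci_high`, `p`, `n`, `k` and the
#'   mean squares `msr`, `msc`, `mse`.
#' @examples
#' icc21(cbind(c(9, 8, 5, 2), c(10, 8, 6, 3)))$icc
#' @export
icc21 <- function(values, alpha = 0.05) {
  x <- as.matrix(values)
  if (anyNA(x))
    stop("incomplete table: ICC(2,1) requires complete data", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2)
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  grand <- mean(x)
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)            # subjects
  ssc <- n * sum((colm - grand)^2)            # raters
  sse <- sum((x - outer(rowm, colm, "+") + grand)^2)  # residual
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr == 0 && mse == 0)
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, n = n, k = k, msr = msr, msc = msc,
                mse = mse))
  icc <- (msr - mse) / denom
  ## F test of ICC = 0
  fobs <- msr / mse
  p <- stats::pf(fobs, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  ## McGraw-Wong CI for ICC(A,1)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci_low = lo, ci_high = hi, p = p, n = n, k = k,
       msr = msr, msc = msc, mse = mse)
}

#' Full agreement report for one paired series
#'
#' Combines [blandAltman()], [accuracySummary()] and [icc21()] (the two
#' series treated as two raters).
#'
#' @inheritParams blandAltman
#' @param alpha ICC confidence level parameter.
#' @return one-row data.frame with columns `bias, loa_low, loa_high, mae,
#'   rmse, r2, beta_origin, icc21, icc_ci_low, icc_ci_high, icc_p, n`.
#' @export
agreementReport <- function(reference, test, alpha = 0.05) {
  ba <- blandAltman(reference, test)
  ac <- accuracySummary(reference, test)
  ic <- icc21(cbind(reference, test), alpha = alpha)
  data.frame(bias = ba[["bias"]], loa_low = ba[["loa_low"]],
             loa_high = ba[["loa_high"]], mae = ba[["mae"]],
             rmse = ba[["rmse"]], r2 = ac[["r2"]],
             beta_origin = ac[["beta_origin"]], icc21 = ic$icc,
             icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
             icc_p = ic$p, n = ba[["n"]])
}

#' Per-muscle reliability report between two measure tables
#'
#' Takes two `MuscleMeasures`-style tables (e.g. ground truth and CNN, or
#' two raters) covering the same scans, matches rows on
#' `(scan_id, label)`, and produces one [agreementReport()] row per label
#' and measure (MFI and volume). Rows whose MFI is flagged undefined in
#' either table are dropped for the MFI series.
#'
#' @param measures_a,measures_b data.frames with columns `scan_id, label,
#'   group, side, mfi_percent, volume_ml` ([measureAll()] output, several
#'   scans concatenated). `measures_a` is the reference.
#' @param alpha ICC confidence level parameter.
#' @return data.frame with one row per (label, measure) and the
#'   [agreementReport()] columns.
#' @export
reliabilityReport <- function(measures_a, measures_b, alpha = 0.05) {
  key_a <- paste(measures_a$scan_id, measures_a$label)
  key_b <- paste(measures_b$scan_id, measures_b$label)
  if (!setequal(key_a, key_b) || anyDuplicated(key_a) || anyDuplicated(key_b)) {
    off <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
    stop(sprintf("unmatched (scan_id, label) rows: %s",
                 paste(unique(off), collapse = "; ")), call. = FALSE)
  }
  measures_b <- measures_b[match(key_a, key_b), , drop = FALSE]
  rows <- list()
  for (lab in sort(unique(measures_a$label))) {
    ia <- measures_a$label == lab
    sub_a <- measures_a[ia, ]; sub_b <- measures_b[ia, ]
    for (meas in c("mfi_percent", "volume_ml")) {
      va <- sub_a[[meas]]; vb <- sub_b[[meas]]
      ok <- !is.na(va) & !is.na(vb)
      if (sum(ok) < 2) next
      rep1 <- agreementReport(va[ok], vb[ok], alpha = alpha)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(label = lab, group = sub_a$group[1], side = sub_a$side[1],
                   measure = if (meas == "mfi_percent") "MFI" else "volume",
                   stringsAsFactors = FALSE), rep1)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
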