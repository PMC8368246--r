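## Cohort-level MFI characterization on per-subject tables of
## bilaterally averaged MFI: pairwise paired t-tests between muscle
## groups, one-way ANCOVA of sex (covariates age and BMI) with estimated
## marginal means, two-tailed partial Pearson correlations, and a
## repeated-measures ANCOVA (muscle group within subjects, sex between,
## age and BMI covariates) with Greenhouse-Geisser correction. No
## multiple-comparison correction is applied anywhere (the analyses are
## exploratory by design).

## pull the per-group MFI matrix out of a cohort table
.cohortMatrix <- function(table, groups = NULL) {
  if (is.null(groups))
    groups <- setdiff(names(table), c("subject", "sex", "age", "bmi"))
  missing <- setdiff(groups, names(table))
  if (length(missing))
    stop("cohort table lacks group columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  as.matrix(table[, groups, drop = FALSE])
}

#' Pairwise paired t-tests between muscle groups
#'
#' Classical two-tailed paired t-test for every pair of muscle-group MFI
#' columns; no multiplicity correction. Zero-variance difference series
#' are flagged rather than tested.
#'
#' @param table cohort data.frame (columns `subject`, `sex`, `age`,
#'   `bmi`, one MFI column per group).
#' @param groups group columns to compare (default: all non-covariate
#'   columns).
#' @return data.frame with one row per pair: `group1, group2, mean_diff,
#'   t, df, p, flag`.
#' @export
pairedGroupTests <- function(table, groups = NULL) {
  y <- .cohortMatrix(table, groups)
  if (ncol(y) < 2 || nrow(y) < 3)
    stop("need at least 2 groups and 3 subjects", call. = FALSE)
  gs <- colnames(y)
  rows <- list()
  for (i in seq_len(ncol(y) - 1)) {
    for (j in (i + 1):ncol(y)) {
      d <- y[, i] - y[, j]
      if (stats::sd(d) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          group1 = gs[i], group2 = gs[j], mean_diff = mean(d),
          t = if (all(d == 0)) 0 else NA_real_, df = length(d) - 1L,
          p = if (all(d == 0)) 1 else NA_real_,
          flag = "zero_variance", stringsAsFactors = FALSE)
      } else {
        tt <- stats::t.test(y[, i], y[, j], paired = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          group1 = gs[i], group2 = gs[j],
          mean_diff = unname(tt$estimate), t = unname(tt$statistic),
          df = unname(tt$parameter), p = tt$p.value, flag = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANCOVA of sex on MFI with covariates age and BMI
#'
#' Multiple linear regression `MFI ~ sex + age + bmi` with sex coded
#' female = 1, male = 0, so a positive coefficient means higher female
#' MFI. Marginal means are the model predictions for each sex at the
#' sample means of age and BMI.
#'
#' @param table cohort data.frame.
#' @param group name of the MFI column to analyse, or `"all"` (default)
#'   for the across-group mean MFI.
#' @param alpha confidence level parameter for the effect CI.
#' @return list with `estimate` (female - male, %), `se`, `ci`
#'   (length 2), `F`, `p`, `emm` (data.frame of sex, marginal mean, se)
#'   and the fitted `model`.
#' @export
sexAncova <- function(table, group = "all", alpha = 0.05) {
  if (length(unique(table$sex)) < 2)
    stop("both sexes must be present", call. = FALSE)
  y <- if (identical(group, "all")) rowMeans(.cohortMatrix(table)) else
    .cohortMatrix(table, group)[, 1]
  dat <- data.frame(y = y, female = as.numeric(table$sex == "F"),
                    age = table$age, bmi = table$bmi)
  ## constant covariates carry no information and would alias the fit
  covs <- c("age", "bmi")[c(stats::var(dat$age) > 0,
                            stats::var(dat$bmi) > 0)]
  fml <- stats::reformulate(c("female", covs), response = "y")
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)$coefficients
  est <- sm["female", "Estimate"]
  se <- sm["female", "Std. Error"]
  tcrit <- stats::qt(1 - alpha / 2, df = fit$df.residual)
  fval <- (est / se)^2
  p <- sm["female", "Pr(>|t|)"]
  nd <- data.frame(female = c(1, 0), age = mean(dat$age),
                   bmi = mean(dat$bmi))
  pr <- stats::predict(fit, newdata = nd, se.fit = TRUE)
  emm <- data.frame(sex = c("F", "M"), emmean = as.numeric(pr$fit),
                    se = as.numeric(pr$se.fit), stringsAsFactors = FALSE)
  list(estimate = est, se = se, ci = c(est - tcrit * se, est + tcrit * se),
       F = fval, p = p, df = c(1, fit$df.residual), emm = emm,
       model = fit)
}

#' Two-tailed partial Pearson correlation
#'
#' Correlation of the residuals of `x` and `y` after regressing each on
#' the control variables (with intercept). With an empty control set
#' this is the plain Pearson correlation. The p value uses the t
#' transform with `n - n_controls - 2` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param controls data.frame (or NULL) of control variables.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
partialCorr <- function(x, y, controls = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  q <- 0L
  if (!is.null(controls) && NCOL(controls) > 0) {
    cm <- as.matrix(as.data.frame(controls))
    if (nrow(cm) != n) stop("controls length mismatch", call. = FALSE)
    q <- ncol(cm)
    X <- cbind(1, cm)
    if (qr(X)$rank < ncol(X))
      stop("collinear controls", call. = FALSE)
    x <- stats::lsfit(cm, x)$residuals
    y <- stats::lsfit(cm, y)$residuals
  }
  if (n <= q + 2) stop("need n > n_controls + 2", call. = FALSE)
  r <- stats::cor(x, y)
  df <- n - q - 2L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df, n = n)
}

#' Repeated-measures ANCOVA with Greenhouse-Geisser correction
#'
#' Muscle group is the within-subject factor, sex the between-subject
#' factor, age and BMI (mean-centred) the covariates. Implemented via
#' the multivariate approach: the wide MFI matrix is regressed on sex
#' and the covariates; within-subject effects are tested on orthonormal
#' group contrasts (univariate split-plot F from the trace of the
#' hypothesis and error SSP matrices), with sphericity handled by the
#' Greenhouse-Geisser epsilon estimated from the contrast-space residual
#' covariance. The between-subject sex effect is the ANCOVA F on the
#' subject means.
#'
#' @param table cohort data.frame; within-subject rows must be complete
#'   (subjects with missing group MFI are listed and excluded with a
#'   warning).
#' @param groups group columns (default: all).
#' @return list with `within` (data.frame of effect, df1, df2, F, p,
#'   gg_epsilon, df1_gg, df2_gg, p_gg) and `between` (data.frame of
#'   effect, df1, df2, F, p).
#' @export
rmAncova <- function(table, groups = NULL) {
  y_all <- .cohortMatrix(table, groups)
  keep <- stats::complete.cases(y_all) & !is.na(table$age) &
    !is.na(table$bmi) & !is.na(table$sex)
  if (!all(keep)) {
    warning(sprintf("excluding %d incomplete subject(s): %s", sum(!keep),
                    paste(table$subject[!keep], collapse = ", ")),
            call. = FALSE)
    table <- table[keep, , drop = FALSE]
    y_all <- y_all[keep, , drop = FALSE]
  }
  n <- nrow(y_all); g <- ncol(y_all)
  if (n < 4 || g < 2)
    stop("need >= 4 complete subjects and >= 2 groups", call. = FALSE)
  female <- as.numeric(table$sex == "F")
  age_c <- table$age - mean(table$age)
  bmi_c <- table$bmi - mean(table$bmi)
  X <- cbind(intercept = 1, female = female, age = age_c, bmi = bmi_c)
  p_rank <- qr(X)$rank
  if (p_rank < ncol(X)) stop("collinear design", call. = FALSE)
  ## orthonormal within-subject contrasts
  M <- .orthonormalContrasts(g)
  B <- solve(crossprod(X), crossprod(X, y_all))
  R <- y_all - X %*% B           # residuals
  dfe <- n - ncol(X)
  ## contrast-space residual SSP and GG epsilon
  E <- t(M) %*% crossprod(R) %*% M
  Sigma <- E / dfe
  eps <- sum(diag(Sigma))^2 / ((g - 1) * sum(Sigma^2))
  eps <- min(1, max(eps, 1 / (g - 1)))
  XtXi <- solve(crossprod(X))
  withinEffect <- function(term, label) {
    L <- matrix(0, nrow = 1, ncol = ncol(X))
    L[1, term] <- 1
    LB <- L %*% B %*% M
    H <- t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB
    df1 <- g - 1
    df2 <- dfe * (g - 1)
    Fv <- (sum(diag(H)) / df1) / (sum(diag(E)) / df2)
    data.frame(effect = label, df1 = df1, df2 = df2, F = Fv,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               gg_epsilon = eps, df1_gg = eps * df1, df2_gg = eps * df2,
               p_gg = stats::pf(Fv, eps * df1, eps * df2,
                                lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  within <- rbind(withinEffect(1L, "group"),
                  withinEffect(2L, "group:sex"),
                  withinEffect(3L, "group:age"),
                  withinEffect(4L, "group:bmi"))
  ## between-subject: ANCOVA on subject means
  ym <- rowMeans(y_all)
  fit <- stats::lm(ym ~ female + age_c + bmi_c)
  sm <- summary(fit)$coefficients
  tv <- sm["female", "t value"]
  between <- data.frame(effect = "sex", df1 = 1, df2 = fit$df.residual,
                        F = tv^2, p = sm["female", "Pr(>|t|)"],
                        stringsAsFactors = FALSE)
  rownames(within) <- NULL
  list(within = within, between = between)
}

## orthonormal polynomial contrasts for g levels (g x (g-1), M'M = I)
.orthonormalContrasts <- function(g) {
  M <- stats::contr.poly(g)
  sw <- sqrt(colSums(M^2))
  sweep(M, 2, sw, "/")
}
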