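test_that("pairedGroupTests: identical and degenerate columns", {
  set.seed(21)
  tab <- generateCohort(cohortSpec(n_subjects = 20L, seed = 1L))
  tab$B <- tab$MFSS          # identical copy
  out <- pairedGroupTests(tab, groups = c("MFSS", "B"))
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  # constant offset, zero noise: zero-variance differences are flagged
  tab$C <- tab$MFSS + 2
  out2 <- pairedGroupTests(tab, groups = c("MFSS", "C"))
  expect_equal(out2$flag, "zero_variance")
  expect_true(is.na(out2$p))
  # ordinary pair matches t.test directly
  out3 <- pairedGroupTests(tab, groups = c("MFSS", "TR"))
  tt <- t.test(tab$MFSS, tab$TR, paired = TRUE)
  expect_equal(out3$t, unname(tt$statistic))
  expect_equal(out3$p, tt$p.value)
})

test_that("deep groups test higher than superficial in a strong cohort", {
  tab <- generateCohort(cohortSpec(seed = 4L))
  out <- pairedGroupTests(tab, groups = c("MFSS", "LS"))
  expect_gt(out$mean_diff, 0)
  expect_lt(out$p, 0.001)
})

test_that("sexAncova equals a normal-equations solve on a hand table", {
  tab <- data.frame(subject = paste0("s", 1:6),
                    sex = c("F", "F", "F", "M", "M", "M"),
                    age = c(25, 40, 33, 28, 50, 45),
                    bmi = c(22, 27, 24, 26, 30, 23),
                    MFSS = c(18, 21, 19, 15, 18, 16))
  r <- sexAncova(tab, "MFSS")
  X <- cbind(1, tab$sex == "F", tab$age, tab$bmi)
  beta <- solve(t(X) %*% X, t(X) %*% tab$MFSS)
  expect_equal(r$estimate, beta[2], tolerance = 1e-10)
  # marginal means difference equals the sex coefficient
  expect_equal(r$emm$emmean[1] - r$emm$emmean[2], r$estimate)
  expect_error(sexAncova(tab[tab$sex == "F", ], "MFSS"), "both sexes")
})

test_that("sexAncova recovers a null and an injected effect", {
  tab0 <- generateCohort(cohortSpec(n_subjects = 600L, sex_effect = 0,
                                    seed = 5L))
  r0 <- sexAncova(tab0)
  expect_lt(abs(r0$estimate), 0.5)
  tab1 <- generateCohort(cohortSpec(seed = 6L))   # 1.8% injected
  r1 <- sexAncova(tab1)
  expect_true(r1$ci[1] <= 1.8 && 1.8 <= r1$ci[2])
  expect_equal(r1$F, (r1$estimate / r1$se)^2)
})

test_that("sexAncova with constant covariates reduces to a t-test", {
  set.seed(7)
  tab <- data.frame(subject = paste0("s", 1:30),
                    sex = rep(c("F", "M"), 15),
                    age = 30, bmi = 25,
                    MFSS = rnorm(30, 10, 2) + rep(c(1, 0), 15))
  r <- sexAncova(tab, "MFSS")
  tt <- t.test(MFSS ~ sex, data = tab, var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
})

test_that("partialCorr equals the two-stage residual oracle", {
  set.seed(8)
  n <- 8
  ctl <- data.frame(a = rnorm(n), b = rnorm(n))
  x <- rnorm(n) + ctl$a
  y <- rnorm(n) - ctl$b
  r <- partialCorr(x, y, ctl)
  expect_equal(r$r, oraclePartialCorr(x, y, ctl), tolerance = 1e-12)
  expect_equal(r$df, n - 2 - 2)
  # empty controls: plain Pearson correlation
  r2 <- partialCorr(x, y)
  expect_equal(r2$r, cor(x, y))
  # y = x gives r = 1; collinear controls error
  expect_equal(partialCorr(x, x, ctl)$r, 1)
  expect_error(partialCorr(x, y, data.frame(a = ctl$a, b = 2 * ctl$a)),
               "collinear")
})

test_that("rmAncova matches an explicit-sums oracle under sphericity", {
  set.seed(9)
  n <- 10; g <- 4
  female <- rep(c(1, 0), each = n / 2)
  age <- rnorm(n, 35, 8); bmi <- rnorm(n, 25, 3)
  # compound-symmetric data: iid residuals + subject effect
  y <- matrix(rnorm(n * g, 10, 1), n, g) + rnorm(n, 0, 2) +
    outer(rep(1, n), c(0, 1, 2, 3))
  tab <- data.frame(subject = paste0("s", 1:n),
                    sex = ifelse(female == 1, "F", "M"),
                    age = age, bmi = bmi)
  tab[paste0("g", 1:g)] <- y
  res <- rmAncova(tab, groups = paste0("g", 1:g))
  ## oracle: explicit projection sums in contrast space
  M <- contr.poly(g); M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  X <- cbind(1, female, age - mean(age), bmi - mean(bmi))
  B <- solve(t(X) %*% X) %*% t(X) %*% y
  R <- y - X %*% B
  E <- t(M) %*% t(R) %*% R %*% M
  LB <- (B[1, , drop = FALSE]) %*% M
  H <- t(LB) %*% solve(matrix(solve(t(X) %*% X)[1, 1])) %*% LB
  Fo <- (sum(diag(H)) / (g - 1)) / (sum(diag(E)) / ((n - 4) * (g - 1)))
  w <- res$within[res$within$effect == "group", ]
  expect_equal(w$F, Fo, tolerance = 1e-6)
  # near-spherical data: GG epsilon close to 1
  expect_gt(w$gg_epsilon, 0.6)
  expect_true(all(res$within$p >= 0 & res$within$p <= 1))
  # between-subject df mirror an ANCOVA on subject means (n - 4 residual)
  expect_equal(res$between$df2, n - 4)
})

test_that("rmAncova excludes incomplete subjects with a warning", {
  tab <- generateCohort(cohortSpec(n_subjects = 12L, seed = 10L))
  tab$MFSS[3] <- NA
  expect_warning(res <- rmAncova(tab), "S003")
  expect_equal(res$between$df2, 11 - 4)
})

test_that("rmAncova detects an injected deep-vs-superficial pattern", {
  tab <- generateCohort(cohortSpec(seed = 11L))
  res <- rmAncova(tab)
  w <- res$within[res$within$effect == "group", ]
  expect_lt(w$p_gg, 0.001)
  # estimates invariant to subject row order
  res2 <- rmAncova(tab[sample(nrow(tab)), ])
  expect_equal(res2$within$F, res$within$F)
})
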