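test_that("noiseless phantom reproduces the specified fat fractions exactly", {
  ph <- generatePhantom(phantomSpec(noise_sd = 0))
  m <- measureAll(ph$volume, ph$mask)
  expect_equal(m$mfi_percent, 100 * ph$truth$fat_fraction, tolerance = 1e-12)
  # truth volumes equal muscleVolume on the generated mask
  for (i in seq_len(nrow(ph$truth)))
    expect_equal(ph$truth$volume_ml[i],
                 muscleVolume(ph$mask, ph$truth$label[i]))
})

test_that("phantom generation is a pure function of its spec", {
  s <- phantomSpec(noise_sd = 5, seed = 7L)
  a <- generatePhantom(s); b <- generatePhantom(s)
  expect_identical(fatSignal(a$volume), fatSignal(b$volume))
  expect_identical(labelArray(a$mask), labelArray(b$mask))
  s2 <- phantomSpec(noise_sd = 5, seed = 8L)
  expect_false(identical(fatSignal(a$volume),
                         fatSignal(generatePhantom(s2)$volume)))
})

test_that("noiseless phantom is mirror-symmetric up to label swap", {
  ph <- generatePhantom(phantomSpec(noise_sd = 0))
  mir <- mirrorLR(list(fat = fatSignal(ph$volume),
                       water = waterSignal(ph$volume)), ph$mask)
  expect_identical(mir$images$fat, fatSignal(ph$volume))
  expect_identical(labelArray(mir$mask), labelArray(ph$mask))
})

test_that("overlapping muscle geometry is rejected", {
  geo <- .defaultGeometry <- DixonMFI:::.defaultGeometry()
  geo$x_off[geo$group == "LC"] <- geo$x_off[geo$group == "MFSS"]
  geo$y_cen[geo$group == "LC"] <- geo$y_cen[geo$group == "MFSS"]
  expect_error(generatePhantom(phantomSpec(geometry = geo, noise_sd = 0)),
               "overlapping geometry")
})

test_that("rician noise option yields non-negative echo magnitudes", {
  ph <- generatePhantom(phantomSpec(noise_sd = 5, noise_model = "rician",
                                    seed = 3L))
  expect_true(all(inPhase(ph$volume) >= 0))
  expect_true(all(outOfPhase(ph$volume) >= 0))
})

test_that("perturbMask with zero rates is the identity", {
  ph <- generatePhantom(phantomSpec(noise_sd = 0))
  out <- perturbMask(ph$mask, raterPerturbSpec(boundary_shift = 0L,
                                               flip_rate = 0))
  expect_identical(labelArray(out), labelArray(ph$mask))
})

test_that("dilation-only perturbation increases every label volume", {
  ph <- generatePhantom(phantomSpec(noise_sd = 0))
  out <- perturbMask(ph$mask,
                     raterPerturbSpec(boundary_shift = 1L, morph_prob = 1,
                                      morph_mode = "dilate", seed = 5L))
  for (lab in 1:14)
    expect_gt(muscleVolume(out, lab), muscleVolume(ph$mask, lab))
  # erosion decreases
  ero <- perturbMask(ph$mask,
                     raterPerturbSpec(boundary_shift = 1L, morph_prob = 1,
                                      morph_mode = "erode", seed = 5L))
  for (lab in 1:14)
    expect_lt(muscleVolume(ero, lab), muscleVolume(ph$mask, lab))
})

test_that("perturbMask is reproducible and never invents labels", {
  ph <- generatePhantom(phantomSpec(noise_sd = 0))
  sp <- raterPerturbSpec(boundary_shift = 2L, morph_prob = 0.8,
                         flip_rate = 0.1, seed = 21L)
  a <- perturbMask(ph$mask, sp)
  b <- perturbMask(ph$mask, sp)
  expect_identical(labelArray(a), labelArray(b))
  expect_true(all(unique(as.vector(labelArray(a))) %in%
                    c(0L, unique(as.vector(labelArray(ph$mask))))))
})

test_that("generateCohort reproduces its generative parameters", {
  # all effects and noise off: every subject sits at the group baselines
  s0 <- cohortSpec(sex_effect = 0, age_slope_deep = 0,
                   age_slope_superficial = 0, subject_sd = 0,
                   residual_sd = 0, seed = 2L)
  tab0 <- generateCohort(s0)
  expect_equal(nrow(tab0), 84L)
  expect_equal(sum(tab0$sex == "F"), 61L)
  for (g in names(s0$baseline))
    expect_true(all(tab0[[g]] == s0$baseline[[g]]))
  # null age slope: partial correlation with age is near zero at n = 500
  s1 <- cohortSpec(n_subjects = 500L, age_slope_deep = 0,
                   age_slope_superficial = 0, seed = 3L)
  tab1 <- generateCohort(s1)
  pc <- partialCorr(tab1$MFSS, tab1$age,
                    data.frame(female = tab1$sex == "F", bmi = tab1$bmi))
  expect_lt(abs(pc$r), 0.1)
  # ages respect the truncation range
  expect_true(all(tab1$age >= 18 & tab1$age <= 65))
})

test_that("cohort generator is deterministic given the seed", {
  a <- generateCohort(cohortSpec(seed = 9L))
  b <- generateCohort(cohortSpec(seed = 9L))
  expect_identical(a, b)
})
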