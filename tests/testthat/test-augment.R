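test_that("mirrorLR is an involution and swaps paired labels", {
  ph <- generatePhantom(phantomSpec(noise_sd = 2, seed = 6L))
  imgs <- list(ip = inPhase(ph$volume), oop = outOfPhase(ph$volume))
  m1 <- mirrorLR(imgs, ph$mask)
  m2 <- mirrorLR(m1$images, m1$mask)
  expect_identical(m2$images$ip, imgs$ip)
  expect_identical(m2$images$oop, imgs$oop)
  expect_identical(labelArray(m2$mask), labelArray(ph$mask))
  # a voxel labelled 2 (MFSS left) maps to 1 (MFSS right) at the
  # mirrored coordinate
  lab <- labelArray(ph$mask)
  idx <- which(lab == 2L, arr.ind = TRUE)[1, ]
  nx <- dim(lab)[1]
  expect_identical(labelArray(m1$mask)[nx + 1 - idx[1], idx[2], idx[3]],
                   1L)
  # per-group left/right volume multiset preserved
  for (g in seq_len(7)) {
    labs <- c(schemeGroups(defaultLabelScheme())$left[g],
              schemeGroups(defaultLabelScheme())$right[g])
    before <- sort(c(sum(lab == labs[1]), sum(lab == labs[2])))
    after <- sort(c(sum(labelArray(m1$mask) == labs[1]),
                    sum(labelArray(m1$mask) == labs[2])))
    expect_identical(before, after)
  }
  # unpaired mask labels are an error
  lab[1, 1, 1] <- 99L
  expect_error(mirrorLR(imgs, SegmentationMask(lab)), "not in scheme")
})

test_that("elasticDeform: identity at sigma 0, label subset, determinism", {
  ph <- generatePhantom(phantomSpec(noise_sd = 0))
  imgs <- list(ip = inPhase(ph$volume))
  e0 <- elasticDeform(imgs, ph$mask, sigma = 0)
  expect_identical(e0$images$ip, imgs$ip)
  e1 <- elasticDeform(imgs, ph$mask, control_points = 3, sigma = 2,
                      seed = 9L)
  expect_true(all(unique(as.vector(labelArray(e1$mask))) %in%
                    unique(as.vector(labelArray(ph$mask)))))
  expect_equal(dim(e1$images$ip), dim(imgs$ip))
  e2 <- elasticDeform(imgs, ph$mask, control_points = 3, sigma = 2,
                      seed = 9L)
  expect_identical(e1$images$ip, e2$images$ip)
  e3 <- elasticDeform(imgs, ph$mask, control_points = 3, sigma = 2,
                      seed = 10L)
  expect_false(identical(e1$images$ip, e3$images$ip))
})

test_that("randomAffine: identity at zero ranges; scaling tracks volume", {
  ph <- generatePhantom(phantomSpec(noise_sd = 0))
  imgs <- list(ip = inPhase(ph$volume))
  a0 <- randomAffine(imgs, ph$mask, scale_percent = 0,
                     rot_deg = c(0, 0, 0), seed = 1L)
  expect_equal(a0$images$ip, imgs$ip, tolerance = 1e-12)
  expect_identical(labelArray(a0$mask), labelArray(ph$mask))
  # exact +2.5% scaling along one long axis: the voxel count grows by
  # the analytic scale factor once the extent dwarfs the voxel size
  d <- c(200L, 24L, 8L)
  slab <- array(0L, d)
  slab[21:180, 7:18, 3:6] <- 1L
  sm <- SegmentationMask(slab, c(1, 1, 1))
  sc <- DixonMFI:::applyAffineWarp(list(), sm, scales = c(1.025, 1, 1))
  ratio <- sum(labelArray(sc$mask) == 1L) / sum(slab == 1L)
  expect_equal(ratio, 1.025, tolerance = 0.005)
  # rotations preserve volume of an interior blob within 2%
  d2 <- c(40L, 40L, 20L)
  cube <- array(0L, d2)
  cube[11:30, 11:30, 6:15] <- 1L
  cm <- SegmentationMask(cube, c(1, 1, 1))
  rot <- DixonMFI:::applyAffineWarp(list(), cm,
                                    angles_rad = c(2.5, 2.5, 5) * pi / 180)
  expect_equal(sum(labelArray(rot$mask) == 1L) / sum(cube == 1L), 1,
               tolerance = 0.02)
})

test_that("augmentDataset: size, identity config, uniform source usage", {
  ph <- lapply(1:7, function(i)
    generatePhantom(deskPhantomSpec(seed = i, noise_sd = 1)))
  ds <- lapply(ph, function(p) list(volume = p$volume, mask = p$mask))
  scheme <- deskPhantomSpec()$scheme
  expect_length(augmentDataset(ds, augmentationConfig(n_augmented = 0L),
                               scheme), 0L)
  cfg_id <- augmentationConfig(mirror_prob = 0, sigma = 0,
                               scale_percent = 0, rot_lr_deg = 0,
                               rot_ap_deg = 0, rot_si_deg = 0,
                               n_augmented = 3L, seed = 2L)
  out <- augmentDataset(ds, cfg_id, scheme)
  for (s in out) {
    src <- ds[[s$provenance$source]]
    expect_equal(fatSignal(s$volume), fatSignal(src$volume),
                 tolerance = 1e-12)
    expect_identical(labelArray(s$mask), labelArray(src$mask))
  }
  cfg <- augmentationConfig(n_augmented = 40L, sigma = 1, seed = 3L)
  out2 <- augmentDataset(ds, cfg, scheme)
  usage <- table(vapply(out2, function(s) s$provenance$source, numeric(1)))
  expect_length(usage, 7L)
  expect_lt(max(usage) / min(usage), 2)
  # augmented grids keep shape and integer labels
  expect_identical(dim(out2[[1]]$mask), dim(ds[[1]]$mask))
  expect_type(labelArray(out2[[1]]$mask), "integer")
})

test_that("histogram standardization is monotone and alignment-correct", {
  set.seed(12)
  img <- array(rgamma(4000, 2, 0.1), c(20, 20, 10))
  lm1 <- fitLandmarks(list(img))
  std <- histogramStandardize(img, lm1)
  # single-image fit: identity within interpolation tolerance
  expect_equal(std, img, tolerance = 0.02)
  # order preservation
  v <- as.vector(img); s <- as.vector(std)
  o <- order(v)
  expect_true(all(diff(s[o]) >= -1e-9))
  # two images differing by a linear transform map near-identically
  img2 <- 3 * img + 50
  lm2 <- fitLandmarks(list(img, img2))
  s1 <- histogramStandardize(img, lm2)
  s2 <- histogramStandardize(img2, lm2)
  expect_lt(max(abs(s1 - s2)), 0.05 * diff(range(s1)))
  # constant image warns and returns unchanged
  cst <- array(5, c(3, 3, 3))
  expect_warning(out <- histogramStandardize(cst, lm2), "constant")
  expect_identical(out, cst)
})

test_that("normalizeLabels maps schemes to contiguous indices invertibly", {
  ph <- generatePhantom(phantomSpec(noise_sd = 0))
  nl <- normalizeLabels(ph$mask)
  # default scheme: identity mapping
  expect_identical(labelArray(nl$mask), labelArray(ph$mask))
  expect_equal(nl$lookup$index, nl$lookup$label)
  # sparse scheme
  sch <- MuscleLabelScheme(data.frame(group = c("A", "B"),
                                      left = c(5L, 9L),
                                      right = c(NA, NA)))
  a <- array(0L, c(2, 2, 1)); a[1] <- 5L; a[2] <- 9L
  nl2 <- normalizeLabels(SegmentationMask(a), sch)
  expect_equal(sort(unique(as.vector(labelArray(nl2$mask)))), c(0L, 1L, 2L))
  back <- denormalizeLabels(nl2$mask, nl2$lookup)
  expect_identical(labelArray(back), a)
  a[4] <- 7L
  expect_error(normalizeLabels(SegmentationMask(a), sch), "unknown")
})
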