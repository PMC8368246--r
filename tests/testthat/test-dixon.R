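test_that("composeDixon implements IP = W + F and OOP = W - F", {
  w <- array(3, c(2, 2, 2)); f <- array(1, c(2, 2, 2))
  cd <- composeDixon(w, f)
  expect_equal(cd$ip, array(4, c(2, 2, 2)))
  expect_equal(cd$oop, array(2, c(2, 2, 2)))
  # zero fat: both echoes equal water
  cd0 <- composeDixon(w, array(0, c(2, 2, 2)))
  expect_equal(cd0$ip, w)
  expect_equal(cd0$oop, w)
  expect_error(composeDixon(w, array(1, c(2, 2, 3))), "shape mismatch")
})

test_that("decomposeDixon inverts composeDixon to machine precision", {
  set.seed(11)
  w <- array(runif(120, 0, 100), c(6, 5, 4))
  f <- array(runif(120, 0, 100), c(6, 5, 4))
  cd <- composeDixon(w, f)
  dc <- decomposeDixon(cd$ip, cd$oop)
  expect_equal(dc$fat, f, tolerance = 0)
  expect_equal(dc$water, w, tolerance = 0)
  expect_identical(dc$n_negative, 0L)
  # printed substitution examples
  d2 <- decomposeDixon(array(4, c(1, 1, 1)), array(2, c(1, 1, 1)))
  expect_equal(as.numeric(d2$fat), 1)
  expect_equal(as.numeric(d2$water), 3)
  d3 <- decomposeDixon(array(5, c(2, 2, 1)), array(5, c(2, 2, 1)))
  expect_true(all(d3$fat == 0))
  # pure fat voxel
  d4 <- decomposeDixon(array(10, c(1, 1, 1)), array(-10, c(1, 1, 1)))
  expect_equal(as.numeric(d4$fat), 10)
  expect_equal(as.numeric(d4$water), 0)
})

test_that("negative decomposition values are counted, kept, or clipped", {
  ip <- array(c(1, 1), c(2, 1, 1))
  oop <- array(c(3, 0), c(2, 1, 1))   # fat = (1-3)/2 = -1 at voxel 1
  expect_warning(dc <- decomposeDixon(ip, oop), "negative")
  expect_equal(dc$n_negative, 1L)
  expect_equal(as.numeric(dc$fat), c(-1, 0.5))
  dc2 <- decomposeDixon(ip, oop, clip = TRUE)
  expect_equal(as.numeric(dc2$fat), c(0, 0.5))
  expect_equal(dc2$n_negative, 1L)
})

test_that("muscleMFI is the ratio-of-means percentage", {
  m <- SegmentationMask(array(1L, c(2, 1, 1)))
  v <- DixonVolume(array(20, c(2, 1, 1)), array(60, c(2, 1, 1)))
  expect_equal(muscleMFI(v, m, 1L), 25)
  # heterogeneous region: mean fat 20, mean water 80 -> 20%
  v2 <- DixonVolume(array(c(10, 30), c(2, 1, 1)),
                    array(c(70, 90), c(2, 1, 1)))
  expect_equal(muscleMFI(v2, m, 1L), 20)
  # ratio of means, not mean of ratios (those would be 12.5% and 25%)
  expect_false(isTRUE(all.equal(muscleMFI(v2, m, 1L),
                                mean(c(100 * 10 / 80, 100 * 30 / 120)))))
  # invariance under global rescaling
  v3 <- DixonVolume(7.3 * fatSignal(v2), 7.3 * waterSignal(v2))
  expect_equal(muscleMFI(v3, m, 1L), muscleMFI(v2, m, 1L))
})

test_that("muscleMFI flags empty labels and non-positive denominators", {
  m <- SegmentationMask(array(1L, c(2, 1, 1)))
  v <- DixonVolume(array(1, c(2, 1, 1)), array(1, c(2, 1, 1)))
  r <- muscleMFI(v, m, 5L)
  expect_true(is.na(r))
  expect_identical(attr(r, "flag"), "empty_label")
  vz <- DixonVolume(array(-1, c(2, 1, 1)), array(1, c(2, 1, 1)))
  expect_warning(rz <- muscleMFI(vz, m, 1L), "non-positive")
  expect_true(is.na(rz))
})

test_that("muscleVolume converts voxel counts to ml", {
  a <- array(0L, c(10, 10, 10)); a[seq_len(1000)] <- 1L
  expect_equal(muscleVolume(SegmentationMask(a, c(0.7, 0.7, 3.0)), 1L),
               1.47)
  expect_equal(muscleVolume(SegmentationMask(a, c(1, 1, 1)), 2L), 0)
  b <- array(0L, c(2, 1, 1)); b[1] <- 1L
  expect_equal(muscleVolume(SegmentationMask(b, c(1, 1, 1)), 1L), 0.001)
})

test_that("measureAll yields one row per scheme label and flags empties", {
  ph <- generatePhantom(phantomSpec(noise_sd = 0))
  m <- measureAll(ph$volume, ph$mask)
  expect_equal(nrow(m), 14L)
  expect_equal(m$label, 1:14)
  # only labels 1 and 2 present
  lab <- labelArray(ph$mask)
  lab[!(lab %in% c(1L, 2L))] <- 0L
  m2 <- measureAll(ph$volume, SegmentationMask(lab, voxelSpacing(ph$mask)))
  expect_equal(nrow(m2), 14L)
  expect_equal(sum(m2$flag == "empty_label"), 12L)
  # unknown labels warn and are excluded
  lab[1, 1, 1] <- 99L
  expect_warning(
    m3 <- measureAll(ph$volume,
                     SegmentationMask(lab, voxelSpacing(ph$mask))),
    "not in scheme")
  expect_false(99 %in% m3$label)
})

test_that("mirroring a phantom exchanges left/right measures", {
  ph <- generatePhantom(phantomSpec(noise_sd = 0))
  m <- measureAll(ph$volume, ph$mask)
  mir <- mirrorLR(list(fat = fatSignal(ph$volume),
                       water = waterSignal(ph$volume)), ph$mask)
  vol_m <- DixonVolume(mir$images$fat, mir$images$water,
                       voxelSpacing(ph$volume))
  m2 <- measureAll(vol_m, mir$mask)
  g <- schemeGroups(defaultLabelScheme())
  for (i in seq_len(nrow(g))) {
    expect_equal(m2$mfi_percent[m2$label == g$left[i]],
                 m$mfi_percent[m$label == g$right[i]])
    expect_equal(m2$volume_ml[m2$label == g$left[i]],
                 m$volume_ml[m$label == g$right[i]])
  }
})

test_that("averageBilateral averages sides and honours flags", {
  meas <- data.frame(scan_id = "s", label = c(2L, 1L), group = "MFSS",
                     side = c("left", "right"),
                     mfi_percent = c(10, 20), volume_ml = c(1, 2),
                     voxel_count = c(10L, 20L), flag = "",
                     stringsAsFactors = FALSE)
  sch <- MuscleLabelScheme(data.frame(group = "MFSS", left = 2L,
                                      right = 1L))
  av <- averageBilateral(meas, sch)
  expect_equal(av$mfi_percent, 15)
  expect_equal(av$volume_ml, 3)
  # equal sides unchanged
  meas$mfi_percent <- c(12, 12)
  expect_equal(averageBilateral(meas, sch)$mfi_percent, 12)
  # one side undefined: use the other, flag it
  meas$mfi_percent <- c(NA, 12)
  av2 <- averageBilateral(meas, sch)
  expect_equal(av2$mfi_percent, 12)
  expect_equal(av2$flag, "one_side_undefined")
  # both undefined
  meas$mfi_percent <- c(NA, NA)
  av3 <- averageBilateral(meas, sch)
  expect_true(is.na(av3$mfi_percent))
  expect_equal(av3$flag, "undefined")
})

test_that("volume is additive over disjoint labels", {
  a <- array(0L, c(4, 4, 2))
  a[1:8] <- 1L; a[9:12] <- 2L
  m <- SegmentationMask(a, c(1, 2, 3))
  expect_equal(muscleVolume(m, 1L) + muscleVolume(m, 2L),
               12 * 6 / 1000)
})
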