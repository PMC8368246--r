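# Tiny configurations keep these structural and numerical checks fast;
# the desk-scale training run lives in the acceptance tests.

tinyConfig <- function(n_classes = 3L) {
  denseVNetConfig(input_channels = 2L, n_classes = n_classes,
                  init_features = 3L, growth = c(2L, 2L),
                  block_depth = c(1L, 1L), bottleneck = c(3L, 4L),
                  head_features = 3L, dropout = 0, pool = c(2L, 2L, 2L))
}

test_that("model output has the input spatial shape and n_classes channels", {
  m <- buildDenseVNet(tinyConfig(), seed = 1)
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  fwd <- DixonMFI:::.netForward(m, x)
  expect_equal(dim(fwd$acts[[m$out_node]]), c(8, 8, 4, 3))
  # window not divisible by the downsampling factors is an explicit error
  xb <- array(0, c(7, 8, 4, 2))
  expect_error(DixonMFI:::.netForward(m, xb), "divisible")
  # parameter count is a pure function of the config
  expect_equal(buildDenseVNet(tinyConfig(), seed = 5)$n_params, m$n_params)
  # same seed, same weights; forward is deterministic with dropout 0
  m2 <- buildDenseVNet(tinyConfig(), seed = 1)
  expect_identical(m2$nodes, m$nodes)
  f2 <- DixonMFI:::.netForward(m, x)
  expect_identical(fwd$acts[[m$out_node]], f2$acts[[m$out_node]])
})

test_that("soft-max probabilities are a valid distribution per voxel", {
  m <- buildDenseVNet(tinyConfig(), seed = 2)
  x <- array(rnorm(8 * 8 * 4 * 2, 0, 3), c(8, 8, 4, 2))
  seg <- DixonMFI:::.segmentArray(m, x)
  sums <- apply(seg$prob, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(seg$prob >= 0 & seg$prob <= 1))
  expect_true(all(seg$idx %in% 0:2))
})

test_that("diceHingeLoss: perfect prediction, closed form, monotonicity", {
  # perfect one-hot prediction -> loss 0
  y <- array(c(0L, 1L, 1L, 0L), c(2, 2, 1))
  p <- array(0, c(2, 2, 1, 2))
  p[, , , 1] <- (labelArray(SegmentationMask(y)) == 0) * 1
  p[, , , 2] <- (y == 1) * 1
  expect_equal(as.numeric(diceHingeLoss(p, y, 0.1)), 0)
  # uniform 0.5 over 2 classes, target all class 1 over n voxels:
  # soft dice = 2 * (0.5 n) / (0.5 n + n) = 2/3, loss = 1/3
  n <- 8
  y1 <- array(1L, c(2, 2, 2))
  pu <- array(0.5, c(2, 2, 2, 2))
  expect_equal(as.numeric(diceHingeLoss(pu, y1, 0)), 1 / 3)
  # hinge clamps small losses to zero
  pg <- array(0, c(2, 2, 2, 2)); pg[, , , 2] <- 0.95; pg[, , , 1] <- 0.05
  # soft dice = 2*.95n/(n + n) = 0.95, loss .05 < margin .1 -> clamped
  expect_equal(as.numeric(diceHingeLoss(pg, y1, 0.1)), 0)
  expect_gt(as.numeric(diceHingeLoss(pg, y1, 0)), 0)
  # loss decreases as probability mass moves toward the target
  y2 <- array(c(1L, 0L), c(2, 1, 1))
  losses <- vapply(seq(0.1, 0.9, 0.1), function(a) {
    p2 <- array(0, c(2, 1, 1, 2))
    p2[1, 1, 1, 2] <- a; p2[1, 1, 1, 1] <- 1 - a
    p2[2, 1, 1, 1] <- a; p2[2, 1, 1, 2] <- 1 - a
    as.numeric(diceHingeLoss(p2, y2, 0))
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  # background-only window is scored on the background class
  y0 <- array(0L, c(2, 1, 1))
  pb <- array(0, c(2, 1, 1, 2)); pb[, , , 1] <- 1
  expect_equal(as.numeric(diceHingeLoss(pb, y0, 0)), 0)
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  m <- buildDenseVNet(tinyConfig(), seed = 3)
  # non-zero biases keep pre-activations off the ReLU kink
  for (i in seq_along(m$nodes))
    if (m$nodes[[i]]$op == "conv")
      m$nodes[[i]]$b <- rnorm(length(m$nodes[[i]]$b), 0, 0.1)
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  y <- array(sample(0:2, 8 * 8 * 4, replace = TRUE), c(8, 8, 4))
  lossOf <- function(mm)
    DixonMFI:::.lossOnLogits(
      DixonMFI:::.netForward(mm, x)$acts[[mm$out_node]], y, 0)$loss
  fwd <- DixonMFI:::.netForward(m, x)
  lo <- DixonMFI:::.lossOnLogits(fwd$acts[[m$out_node]], y, 0)
  pg <- DixonMFI:::.netBackward(m, fwd, lo$dlogits)
  eps <- 1e-5
  for (ci in which(vapply(m$nodes, function(nd) nd$op == "conv",
                          logical(1)))) {
    for (ii in sample(length(m$nodes[[ci]]$w), 2)) {
      m2 <- m; m2$nodes[[ci]]$w[ii] <- m$nodes[[ci]]$w[ii] + eps
      l2 <- lossOf(m2)
      m2$nodes[[ci]]$w[ii] <- m$nodes[[ci]]$w[ii] - eps
      l1 <- lossOf(m2)
      expect_equal(pg[[ci]]$gw[ii], (l2 - l1) / (2 * eps),
                   tolerance = 1e-4)
    }
    m2 <- m; m2$nodes[[ci]]$b[1] <- m$nodes[[ci]]$b[1] + eps
    l2 <- lossOf(m2)
    m2$nodes[[ci]]$b[1] <- m$nodes[[ci]]$b[1] - eps
    l1 <- lossOf(m2)
    expect_equal(pg[[ci]]$gb[1], (l2 - l1) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("training is reproducible and can overfit a single volume", {
  sp <- deskPhantomSpec(seed = 31L)
  sp$grid <- c(16L, 16L, 4L)
  sp$geometry$x_off <- c(2.1, 0)
  sp$geometry$y_cen <- c(7.7, 4.9)
  sp$geometry$rx <- c(0.84, 0.84)
  sp$geometry$ry <- c(0.84, 0.84)
  sp$geometry$z_lo <- c(1L, 1L); sp$geometry$z_hi <- c(4L, 4L)
  ph <- generatePhantom(sp)
  s <- makeTrainingSample(ph$volume, ph$mask, sp$scheme)
  cfg <- tinyConfig(n_classes = 4L)
  tc <- trainingConfig(batch_size = 1L, window = c(16L, 16L, 4L),
                       max_iterations = 40L, eval_every = 10L,
                       patience = 50L, seed = 77L)
  m1 <- trainDenseVNet(buildDenseVNet(cfg, seed = 4), list(s), config = tc)
  m2 <- trainDenseVNet(buildDenseVNet(cfg, seed = 4), list(s), config = tc)
  expect_identical(m1$history$loss, m2$history$loss)
  # loss should drop markedly while overfitting one volume
  expect_lt(mean(tail(m1$history$loss, 5)), mean(head(m1$history$loss, 5)))
  # segmentDixon output: valid probabilities, labels within the scheme
  seg <- segmentDixon(m1, inPhase(ph$volume), outOfPhase(ph$volume),
                      spacing = voxelSpacing(ph$volume))
  sums <- apply(seg$prob, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(unique(as.vector(labelArray(seg$mask))) %in%
                    c(0L, schemeLabels(sp$scheme))))
  # tiled inference agrees in shape and stays a valid distribution
  seg_t <- segmentDixon(m1, inPhase(ph$volume), outOfPhase(ph$volume),
                        spacing = voxelSpacing(ph$volume),
                        window = c(8L, 8L, 4L))
  expect_equal(dim(seg_t$prob), dim(seg$prob))
  expect_true(all(abs(apply(seg_t$prob, 1:3, sum) - 1) < 1e-5))
})

test_that("non-finite loss aborts with diagnostics", {
  sp <- deskPhantomSpec(seed = 32L)
  sp$grid <- c(8L, 8L, 4L)
  sp$geometry$x_off <- c(0.7, 0)
  sp$geometry$y_cen <- c(3.5, 2.1)
  sp$geometry$rx <- c(0.7, 0.7); sp$geometry$ry <- c(0.7, 0.7)
  sp$geometry$z_lo <- c(1L, 1L); sp$geometry$z_hi <- c(4L, 4L)
  ph <- generatePhantom(sp)
  s <- makeTrainingSample(ph$volume, ph$mask, sp$scheme)
  s$x[1] <- NaN
  m <- buildDenseVNet(tinyConfig(n_classes = 4L), seed = 1)
  tc <- trainingConfig(batch_size = 1L, window = c(8L, 8L, 4L),
                       max_iterations = 5L, seed = 1L)
  expect_error(trainDenseVNet(m, list(s), config = tc), "non-finite")
})

test_that("preprocessVolume resamples and pads without cropping", {
  ph <- generatePhantom(deskPhantomSpec(noise_sd = 0))
  # already at target spacing and shape: identity
  idt <- preprocessVolume(ph$volume, ph$mask,
                          target_spacing = voxelSpacing(ph$volume))
  expect_equal(fatSignal(idt$volume), fatSignal(ph$volume))
  expect_identical(labelArray(idt$mask), labelArray(ph$mask))
  # 2x finer in-plane: label set preserved, physical volume within 3%
  fine <- preprocessVolume(ph$volume, ph$mask,
                           target_spacing = c(0.35, 0.35, 3.0))
  expect_true(setequal(unique(as.vector(labelArray(fine$mask))),
                       unique(as.vector(labelArray(ph$mask)))))
  expect_equal(muscleVolume(fine$mask, 2L), muscleVolume(ph$mask, 2L),
               tolerance = 0.03)
  # padding is symmetric zero fill; too-small targets refuse to crop
  pad <- preprocessVolume(ph$volume, ph$mask,
                          target_spacing = voxelSpacing(ph$volume),
                          pad_to = c(56L, 56L, 10L))
  expect_equal(dim(pad$volume), c(56L, 56L, 10L))
  expect_equal(sum(labelArray(pad$mask) != 0),
               sum(labelArray(ph$mask) != 0))
  expect_error(preprocessVolume(ph$volume,
                                target_spacing = voxelSpacing(ph$volume),
                                pad_to = c(40L, 56L, 10L)),
               "refusing to crop")
})
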