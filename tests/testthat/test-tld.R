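staticVideo <- generateProbeVideo(probeVideoSpec(
  nFrames = 20, trajectory = matrix(rep(c(40, 50), each = 20), ncol = 2),
  driftRate = 0.02, seed = 4))

test_that("the detector re-finds the training object in frame 1", {
  st <- tldInit(staticVideo$frames[[1]], staticVideo$boxes[[1]], tldConfig(seed = 1))
  det <- tldDetect(staticVideo$frames[[1]], st)
  expect_gt(nrow(det$candidates), 0)
  ors <- vapply(seq_len(nrow(det$candidates)), function(i)
    overlapRate(BoundingBox(det$candidates$x[i], det$candidates$y[i],
                            det$candidates$w[i], det$candidates$h[i]),
                staticVideo$boxes[[1]]), numeric(1))
  expect_gt(max(ors), 0.8)
  # all candidates stay inside the frame
  expect_true(all(det$candidates$x >= 0 & det$candidates$y >= 0 &
                  det$candidates$x + det$candidates$w <= 160 &
                  det$candidates$y + det$candidates$h <= 120))
})

test_that("an unrelated noise frame produces no confirmed candidates", {
  st <- tldInit(staticVideo$frames[[1]], staticVideo$boxes[[1]], tldConfig(seed = 1))
  set.seed(8)
  noise <- matrix(runif(120 * 160), 120, 160)
  det <- tldDetect(noise, st)
  expect_equal(nrow(det$candidates), 0)
})

test_that("integration handles the trivial tracker/detector combinations", {
  st <- tldInit(staticVideo$frames[[1]], staticVideo$boxes[[1]], tldConfig(seed = 1))
  st$lastScan <- NULL
  empty <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0), fernSum = numeric(0),
                      relSim = numeric(0), consSim = numeric(0))
  keepT <- tldIntegrate(staticVideo$frames[[1]], staticVideo$boxes[[1]], empty, st)
  expect_equal(keepT$source, "tracker")
  expect_equal(boxVec(keepT$box), boxVec(staticVideo$boxes[[1]]))
  none <- tldIntegrate(staticVideo$frames[[1]], NULL, empty, st)
  expect_null(none$box)
  expect_equal(none$source, "absent")
})

test_that("P-N learning grows the model from detector mistakes and never shrinks counters", {
  st <- tldInit(staticVideo$frames[[1]], staticVideo$boxes[[1]], tldConfig(seed = 1))
  det <- tldDetect(staticVideo$frames[[2]], st)
  st <- det$state
  # force every window to a negative ensemble label: overlapping windows
  # become false negatives for the P-expert
  st$ensemble$P[] <- 0L
  st$ensemble <- adaptivePosteriorUpdate(st$ensemble, 0L, 0L)
  st$lastScan$fernSum[!is.na(st$lastScan$fernSum)] <- 0
  nPos0 <- length(st$model$pos)
  st2 <- pnUpdate(st, staticVideo$frames[[2]], staticVideo$boxes[[2]])
  expect_gte(length(st2$model$pos), nPos0 + 1L)
  expect_gt(st2$nPos, st$nPos)
  expect_gte(st2$nTot, st2$nPos)
  # unreliable locations leave the state unchanged
  st3 <- pnUpdate(st2, staticVideo$frames[[2]], BoundingBox(5, 5, 36, 14))
  expect_identical(st3$nPos, st2$nPos)
  expect_identical(st3$ensemble$P, st2$ensemble$P)
})

test_that("a static scene is tracked with high overlap throughout", {
  tr <- trackVideo(staticVideo$frames, staticVideo$boxes[[1]], tldConfig(seed = 1))
  ors <- vapply(1:20, function(t)
    overlapRate(tr$trajectory[[t]], staticVideo$boxes[[t]]), numeric(1))
  expect_true(all(ors >= 0.9))
})

test_that("adaptive subset size zero reproduces the baseline tracker bit for bit", {
  v <- makeDriftVideo(seed = 31, nFrames = 40, occlusionFrames = integer(0))
  base1 <- trackVideo(v$frames, v$boxes[[1]], tldConfig(seed = 2, adaptiveFraction = 0))
  base2 <- trackVideo(v$frames, v$boxes[[1]], tldConfig(seed = 2, adaptiveFraction = 0))
  expect_identical(base1$trajectory, base2$trajectory)
  expect_identical(base1$state$ensemble$posterior, base2$state$ensemble$posterior)
  # no adaptive subset: unseen posterior entries stay exactly 0
  seen <- base1$state$ensemble$P + base1$state$ensemble$N > 0
  expect_true(all(base1$state$ensemble$posterior[!seen] == 0))
  expect_length(base1$state$ensemble$adaptiveIdx, 0L)
})
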