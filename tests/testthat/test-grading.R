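smallGrid <- list(costs = 2^c(0, 6), gammas = 2^c(-8, -2))

test_that("the tissue ROI sits ahead of the probe tip, towards the eye center", {
  frame <- array(0.5, c(200, 200, 3))
  eye <- Ellipse(100, 100, 90, 90, 0)
  probe <- BoundingBox(20, 93, 36, 14)   # pointing right, towards the center
  r <- extractTissueRoi(frame, probe, eye)
  tip <- r$tip
  expect_equal(unname(tip), c(56, 100))
  ctr <- c(r$roi@x + 16, r$roi@y + 16)
  # strictly between tip and eye center
  expect_true(ctr[1] > tip[1] && ctr[1] < 100 + 1e-9)
  expect_equal(dim(r$patch), c(32L, 32L, 3L))

  # degenerate direction: probe centered on the eye center, tie-break -y
  probe2 <- BoundingBox(100 - 18, 100 - 7, 36, 14)
  r2 <- extractTissueRoi(frame, probe2, eye)
  expect_equal(unname(r2$tip), c(100, 93))      # top edge midpoint
  expect_lt(r2$roi@y + 16, 93)                  # ROI extends upwards

  # ROI forced outside the frame fails
  eyeCorner <- Ellipse(5, 5, 100, 100, 0)
  expect_error(extractTissueRoi(array(0.5, c(40, 40, 3)),
                                BoundingBox(25, 25, 10, 10), eyeCorner), "ROI")
})

test_that("the extracted patch carries the tissue color at the tip", {
  v <- makeSurgeryVideo(seed = 33, nFrames = 1, grade = 4)
  r <- extractTissueRoi(v$frames[[1]], v$boxes[[1]], v$iris)
  mu <- apply(r$patch, 3, mean)
  expect_lt(max(abs(mu - defaultTissueColors()[5, ] / 255)), 0.12)
})

test_that("feature vectors follow the pixel + cell-mean layout exactly", {
  uni <- array(rep(c(0.2, 0.5, 0.8), each = 1024), c(32, 32, 3))
  f <- extractFeatures(uni)
  expect_length(f, 3264)
  expect_true(all(f[seq(1, 3264, by = 3)] == 0.2))
  expect_true(all(f[seq(3, 3264, by = 3)] == 0.8))

  half <- array(0, c(32, 32, 3))
  half[, 17:32, ] <- 1   # left half black, right half white
  fh <- extractFeatures(half)
  cellPart <- fh[(3 * 1024 + 1):3264]
  expect_true(all(cellPart %in% c(0, 1)))
  expect_equal(sum(cellPart), 3 * 32)   # half of the 64 cells, 3 channels

  set.seed(4)
  rnd <- array(runif(3072), c(32, 32, 3))
  fr <- extractFeatures(rnd)
  # brute-force averaging oracle over each 4x4 cell
  for (cy in 0:7) for (cx in 0:7) {
    for (ch in 1:3) {
      manual <- mean(rnd[cy * 4 + 1:4, cx * 4 + 1:4, ch])
      expect_identical(fr[3 * 1024 + (cy * 8 + cx) * 3 + ch], manual)
    }
  }
  expect_error(extractFeatures(array(0, c(16, 16, 3))), "32")
})

test_that("zero-noise patches train a perfect, deterministic cascade", {
  p <- generateTissuePatches(tissueColorModel(noiseSd = 0, seed = 2), 8)
  c1 <- trainCascade(p$patches, p$labels, costs = smallGrid$costs,
                     gammas = smallGrid$gammas, seed = 1)
  c2 <- trainCascade(p$patches, p$labels, costs = smallGrid$costs,
                     gammas = smallGrid$gammas, seed = 1)
  expect_identical(c1@cvStage1, c2@cvStage1)
  expect_identical(c1@stage2$cost, c2@stage2$cost)
  expect_identical(c1@stage2$gamma, c2@stage2$gamma)

  preds <- vapply(p$patches, function(q) gradeTissue(q, c1)$grade, integer(1))
  expect_equal(preds, p$labels)

  # cascade contract and Emery-Little color semantics
  normal <- gradeTissue(p$patches[[which(p$labels == 0)[1]]], c1)
  expect_equal(normal$grade, 0L)
  expect_false(normal$stage2Invoked)
  darkYellow <- gradeTissue(p$patches[[which(p$labels == 3)[1]]], c1)
  expect_equal(darkYellow$grade, 3L)
  expect_true(darkYellow$stage2Invoked)
  darkBrown <- gradeTissue(p$patches[[which(p$labels == 5)[1]]], c1)
  expect_equal(darkBrown$grade, 5L)
})

test_that("training fails loudly when a class is missing", {
  p <- generateTissuePatches(tissueColorModel(noiseSd = 0, seed = 2), 2)
  keep <- p$labels != 4
  expect_error(trainCascade(p$patches[keep], p$labels[keep]), "4")
})

test_that("the KNN baseline votes like a brute-force neighbour scan", {
  set.seed(6)
  trainX <- matrix(runif(300 * 20), 300, 20)
  trainY <- sample(0:5, 300, TRUE)
  testX <- matrix(runif(100 * 20), 100, 20)
  mine <- knnBaseline(trainX, trainY, testX, k = 5)
  for (i in 1:100) {
    d <- sqrt(colSums((t(trainX) - testX[i, ])^2))
    nb <- order(d)[1:5]
    votes <- table(trainY[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      md <- vapply(top, function(lb) mean(d[nb][trainY[nb] == as.integer(lb)]),
                   numeric(1))
      top <- top[which.min(md)]
    }
    expect_identical(mine[i], as.integer(top))
  }
  # exact-match query with k = 1 returns that sample's label
  expect_identical(knnBaseline(trainX, trainY, trainX[17, ], k = 1), trainY[17])
  expect_error(knnBaseline(trainX[0, , drop = FALSE], integer(0), testX[1, ]), "empty")
})
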