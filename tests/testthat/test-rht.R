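test_that("distance-constrained sampling honours the pairwise constraint", {
  set.seed(1)
  pts <- cbind(runif(200, 0, 250), runif(200, 0, 250))
  # constraint off: any draw of distinct points is admissible
  g0 <- sampleGroup(pts, 5, 0)
  expect_equal(nrow(g0), 5L)
  expect_equal(anyDuplicated(g0), 0L)
  # infeasible: tight cluster with a large threshold
  tight <- cbind(runif(30, 0, 2), runif(30, 0, 2))
  expect_null(sampleGroup(tight, 5, 10))
  # many draws, exhaustive pairwise check
  for (i in 1:500) {
    g <- sampleGroup(pts, 5, 25)
    if (is.null(g)) next
    expect_gte(min(dist(g)), 25)
  }
})

test_that("ellipse detection recovers a noiseless contour to pixel accuracy", {
  img <- makeEyeImage(seed = 17, noiseFraction = 0)
  el <- detectEllipseRht(img$points, rhtConfig(nSamples = 600, seed = 4))
  expect_true(recoveredIris(el, img$iris))
  expect_lt(abs(el@cx - 128), 2)
  expect_lt(abs(el@a - 60) / 60, 0.05)
})

test_that("pure noise with a high vote threshold yields no detection", {
  set.seed(9)
  noise <- cbind(round(runif(150, 0, 255)), round(runif(150, 0, 255)))
  el <- detectEllipseRht(noise, rhtConfig(nSamples = 400, voteThreshold = 100, seed = 2))
  expect_null(el)
})

test_that("detection is deterministic under a fixed config seed", {
  img <- makeEyeImage(seed = 19, noiseFraction = 0.3)
  cfg <- rhtConfig(nSamples = 500, minPairDistance = 18, seed = 6)
  expect_identical(detectEllipseRht(img$points, cfg), detectEllipseRht(img$points, cfg))
  expect_identical(detectCircleRht(img$points, cfg), detectCircleRht(img$points, cfg))
})

test_that("circle detection recovers circles and rejects elongated ellipses", {
  circ <- makeEyeImage(seed = 23, noiseFraction = 0, iris = Ellipse(128, 128, 50, 50, 0))
  ci <- detectCircleRht(circ$points, rhtConfig(nSamples = 400, seed = 3))
  expect_false(is.null(ci))
  expect_lt(abs(ci@r - 50), 2)

  elong <- makeEyeImage(seed = 23, noiseFraction = 0, iris = Ellipse(128, 128, 60, 30, 0.4))
  d <- detectCircleRht(elong$points, rhtConfig(nSamples = 400, seed = 3), diagnostics = TRUE)
  expect_null(d$circle)
  expect_lt(d$inlierFraction, 0.5)
})

test_that("detectEye cascades circle first, then ellipse", {
  circ <- makeEyeImage(seed = 29, noiseFraction = 0.1, iris = Ellipse(128, 128, 55, 55, 0))
  r1 <- detectEye(circ$image, rhtConfig(nSamples = 800, seed = 2))
  expect_equal(r1$stage, "circle")
  expect_true(recoveredIris(r1$ellipse, circ$iris))

  ell <- makeEyeImage(seed = 29, noiseFraction = 0.1, iris = Ellipse(128, 128, 60, 42, 0.5))
  r2 <- detectEye(ell$image, rhtConfig(nSamples = 1500, seed = 2))
  expect_equal(r2$stage, "ellipse")
  expect_true(recoveredIris(r2$ellipse, ell$iris))

  blank <- matrix(0, 64, 64)
  r3 <- detectEye(blank, rhtConfig(nSamples = 100, seed = 1))
  expect_null(r3$ellipse)
  expect_equal(r3$stage, "none")
})

test_that("anatomical correctness checks both containments", {
  iris <- stdIris(); limbus <- Ellipse(128, 128, 78, 52, 0.3)
  expect_true(detectionCorrect(iris, iris, limbus))
  mid <- Ellipse(128, 128, 69, 46, 0.3)
  expect_true(detectionCorrect(mid, iris, limbus))
  big <- Ellipse(128, 128, 78 * 1.5, 52 * 1.5, 0.3)
  expect_false(detectionCorrect(big, iris, limbus))
  small <- Ellipse(128, 128, 50, 30, 0.3)   # fails to encircle the iris
  expect_false(detectionCorrect(small, iris, limbus))

  # dense-rasterisation oracle for the midway case
  th <- seq(0, 2 * pi, length.out = 720)
  bd <- cbind(128 + 69 * cos(th) * cos(0.3) - 46 * sin(th) * sin(0.3),
              128 + 69 * cos(th) * sin(0.3) + 46 * sin(th) * cos(0.3))
  expect_true(all(ellipseContains(limbus, bd, tol = 1e-7)))
})
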