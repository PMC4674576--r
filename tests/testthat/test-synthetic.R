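test_that("eye image generator emits the specified point counts and geometry", {
  img <- makeEyeImage(seed = 7, noiseFraction = 0.3)
  expect_equal(nrow(img$contourPoints), 200L)
  expect_equal(nrow(img$noisePoints), ceiling(0.3 / 0.7 * 200))
  expect_equal(nrow(img$points), nrow(img$contourPoints) + nrow(img$noisePoints))
  # binary image has ones exactly at the listed points
  expect_equal(sum(img$image), nrow(unique(img$points)))
  expect_true(all(img$image[cbind(img$points[, 2] + 1, img$points[, 1] + 1)] == 1))
  # true-point fraction within one point of 1 - noise fraction
  f <- nrow(img$contourPoints) / nrow(img$points)
  expect_lt(abs(f - 0.7), 1 / nrow(img$points) + 1e-9)
})

test_that("noiseless contour points satisfy the iris conic to quantisation error", {
  img <- makeEyeImage(seed = 3, noiseFraction = 0)
  expect_equal(nrow(img$points), 200L)
  d <- phacovision:::ellipseBoundaryDistance(img$iris, img$points)
  expect_lt(max(d), 1.01)  # rounded to the pixel grid
})

test_that("a circular iris yields equidistant contour points", {
  img <- makeEyeImage(seed = 5, noiseFraction = 0, iris = Ellipse(128, 128, 50, 50, 0))
  r <- sqrt((img$points[, 1] - 128)^2 + (img$points[, 2] - 128)^2)
  expect_true(all(abs(r - 50) <= 1))
})

test_that("generators are pure functions of their specs", {
  s <- eyeImageSpec(c(256, 256), stdIris(), nContourPoints = 150,
                    noiseFraction = 0.2, seed = 7)
  expect_identical(generateEyeImage(s), generateEyeImage(s))

  vspec <- probeVideoSpec(nFrames = 5, driftRate = 0.1, seed = 9)
  expect_identical(generateProbeVideo(vspec), generateProbeVideo(vspec))

  m <- tissueColorModel(noiseSd = 10, seed = 4)
  expect_identical(generateTissuePatches(m, 3), generateTissuePatches(m, 3))
})

test_that("invalid eye specs are rejected with descriptive failures", {
  big <- Ellipse(128, 128, 140, 120, 0)
  expect_error(eyeImageSpec(c(256, 256), big), "image bounds")
  expect_error(eyeImageSpec(c(256, 256), stdIris(),
                            limbus = Ellipse(128, 128, 59, 41, 0.3),
                            noiseFraction = 0.5), "limbus")
  expect_error(eyeImageSpec(c(256, 256), stdIris(), noiseFraction = 1), "noiseFraction")
})

test_that("probe video: static spec gives identical frames, translation moves truth exactly", {
  static <- generateProbeVideo(probeVideoSpec(
    nFrames = 4, trajectory = matrix(rep(c(40, 50), each = 4), ncol = 2),
    driftRate = 0, seed = 2))
  expect_identical(static$frames[[1]], static$frames[[4]])

  n <- 6
  v <- generateProbeVideo(probeVideoSpec(
    nFrames = n, trajectory = cbind(20 + 2 * (0:(n - 1)), 50), driftRate = 0, seed = 2))
  for (t in 2:n) {
    expect_equal(v$boxes[[t]]@x - v$boxes[[t - 1]]@x, 2)
    expect_equal(v$boxes[[t]]@y - v$boxes[[t - 1]]@y, 0)
  }
})

test_that("occlusion frames have absent ground truth and no rendered probe", {
  v <- generateProbeVideo(probeVideoSpec(
    nFrames = 60, occlusionFrames = 50L, driftRate = 0, seed = 2))
  expect_null(v$boxes[[50]])
  expect_false(is.null(v$boxes[[49]]))
  # without the probe the frame equals the pure background frame
  expect_identical(v$frames[[50]],
                   generateProbeVideo(probeVideoSpec(
                     nFrames = 60, occlusionFrames = 1:60, driftRate = 0,
                     seed = 2))$frames[[50]])
})

test_that("empty trajectories are rejected", {
  expect_error(probeVideoSpec(nFrames = 0, trajectory = matrix(numeric(0), 0, 2)),
               "empty")
})

test_that("tissue patches follow the grade color model", {
  m0 <- tissueColorModel(noiseSd = 0, seed = 1)
  p <- generateTissuePatches(m0, 2)
  expect_equal(sort(unique(p$labels)), 0:5)
  expect_equal(as.vector(table(p$labels)), rep(2L, 6))
  g3 <- p$patches[[which(p$labels == 3)[1]]]
  for (ch in 1:3)
    expect_true(all(g3[, , ch] == defaultTissueColors()[4, ch] / 255))

  noisy <- generateTissuePatches(tissueColorModel(noiseSd = 10, seed = 1), 2)
  expect_true(all(vapply(noisy$patches, function(q) all(q >= 0 & q <= 1), logical(1))))
  expect_error(tissueColorModel(means = matrix(1, 6, 3)), "distinct")
})
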