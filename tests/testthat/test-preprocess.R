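test_that("constant frames give no edge points and empty frames fail", {
  expect_equal(nrow(preprocessFrame(matrix(0.5, 40, 40))), 0L)
  expect_error(preprocessFrame(matrix(numeric(0), 0, 0)), "empty")
})

test_that("binary edge maps keep the contour and drop isolated noise", {
  img <- makeEyeImage(seed = 13, noiseFraction = 0.3)
  pts <- preprocessFrame(img$image)
  keyOut <- paste(pts[, 1], pts[, 2])
  keyContour <- paste(img$contourPoints[, 1], img$contourPoints[, 2])
  expect_gte(mean(keyContour %in% keyOut), 0.9)
  # output points lie within image bounds and on lit pixels
  expect_true(all(pts[, 1] >= 0 & pts[, 1] < 256 & pts[, 2] >= 0 & pts[, 2] < 256))
  expect_true(all(img$image[cbind(pts[, 2] + 1, pts[, 1] + 1)] == 1))
})

test_that("gradient edges of a rendered scene trace the iris boundary", {
  v <- makeSurgeryVideo(seed = 21, nFrames = 1)
  pts <- preprocessFrame(v$frames[[1]])
  expect_gt(nrow(pts), 100)
  d <- phacovision:::ellipseBoundaryDistance(v$iris, pts)
  # a solid ring of points near the limbus step edge
  expect_gt(sum(d < 3), 300)
})
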