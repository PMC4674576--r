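test_that("identity input gives zero displacement", {
  v <- generateProbeVideo(probeVideoSpec(
    nFrames = 1, trajectory = cbind(40, 50), probeShape = "rect", seed = 4))
  b <- medianFlow(v$frames[[1]], v$frames[[1]], v$boxes[[1]])
  expect_lt(abs(b@x - v$boxes[[1]]@x), 0.1)
  expect_lt(abs(b@y - v$boxes[[1]]@y), 0.1)
  expect_lt(attr(b, "medianFB"), 0.1)
})

test_that("a translating textured patch is followed to sub-pixel accuracy", {
  v <- makeTranslationVideo(20, c(2, 0), seed = 11)
  for (t in 2:20) {
    b <- medianFlow(v$frames[[t - 1]], v$frames[[t]], v$boxes[[t - 1]])
    expect_false(is.null(b))
    expect_lt(sqrt((b@x - v$boxes[[t]]@x)^2 + (b@y - v$boxes[[t]]@y)^2), 0.5)
  }
})

test_that("median flow fails cleanly when the target texture disappears", {
  v <- generateProbeVideo(probeVideoSpec(
    nFrames = 2, trajectory = matrix(rep(c(40, 50), each = 2), ncol = 2),
    occlusionFrames = 2L, driftRate = 0, seed = 4))
  b <- medianFlow(v$frames[[1]], v$frames[[2]], v$boxes[[1]])
  expect_null(b)
})

test_that("boxes outside the frame are rejected", {
  v <- generateProbeVideo(probeVideoSpec(nFrames = 1, trajectory = cbind(40, 50), seed = 4))
  expect_error(medianFlow(v$frames[[1]], v$frames[[1]], BoundingBox(150, 110, 36, 14)),
               "outside")
})
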