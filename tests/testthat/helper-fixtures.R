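# Shared fixture builders; everything is generated in code, seeded.

stdIris <- function(theta = 0.3, a = 60, b = 40) Ellipse(128, 128, a, b, theta)

makeEyeImage <- function(seed, noiseFraction = 0.3, iris = stdIris(),
                         nContourPoints = 200L) {
  generateEyeImage(eyeImageSpec(c(256L, 256L), iris,
                                nContourPoints = nContourPoints,
                                noiseFraction = noiseFraction, seed = seed))
}

# rigid translation video with a fully textured probe patch
makeTranslationVideo <- function(nFrames, dxdy = c(2, 0), seed = 11L) {
  traj <- cbind(15 + dxdy[1] * (0:(nFrames - 1)),
                40 + dxdy[2] * (0:(nFrames - 1)))
  spec <- probeVideoSpec(frameSize = c(160L + max(traj[, 1]) - min(traj[, 1]) + 60L, 120L),
                         nFrames = nFrames, trajectory = traj, driftRate = 0,
                         probeShape = "rect", seed = seed)
  generateProbeVideo(spec)
}

# needle probe over a drifting background, with an optional occlusion
makeDriftVideo <- function(seed, nFrames = 200L, driftRate = 0.08,
                           occlusionFrames = 120:129) {
  spec <- probeVideoSpec(nFrames = nFrames, driftRate = driftRate,
                         occlusionFrames = occlusionFrames, seed = seed)
  generateProbeVideo(spec)
}

# full surgery scene: circular iris, graded tissue, moving needle probe
makeSurgeryVideo <- function(seed, nFrames = 100L, grade = 3L) {
  iris <- Ellipse(120, 120, 85, 85, 0)
  traj <- cbind(70 + 0.4 * (0:(nFrames - 1)), 100 + 0.15 * (0:(nFrames - 1)))
  spec <- probeVideoSpec(frameSize = c(240L, 240L), nFrames = nFrames,
                         trajectory = traj, driftRate = 0.03, iris = iris,
                         tissueGrade = grade, seed = seed)
  c(generateProbeVideo(spec), list(iris = iris))
}

trajectoryPrecision <- function(traj, gt) {
  trackingPrecisionOf(evaluateTracking(traj, gt))
}

# geometric recovery of a known iris from a detection
recoveredIris <- function(el, iris, centerTol = 2, axisTol = 0.05) {
  !is.null(el) &&
    abs(el@cx - iris@cx) <= centerTol && abs(el@cy - iris@cy) <= centerTol &&
    abs(el@a - iris@a) <= axisTol * iris@a &&
    abs(el@b - iris@b) <= axisTol * iris@b
}

# independent conic through 5 points: SVD null space of the full
# 6-parameter design matrix (a different algorithm than the 5x5 solve)
svdConicOracle <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  M <- cbind(x^2, 2 * x * y, y^2, 2 * x, 2 * y, 1)
  v <- svd(M, nu = 0, nv = 6)$v[, 6]
  if (abs(v[1]) < 1e-12) return(NULL)
  v <- v / v[1]
  ConicParams(v[2], v[3], v[4], v[5], v[6])
}
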