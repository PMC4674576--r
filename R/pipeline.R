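#' Overlap rate of two boxes
#'
#' Intersection area divided by the smaller of the two box areas. This is
#' deliberately more permissive than intersection-over-union: the probe's
#' extent is not sharply defined, so a prediction nested inside (or
#' containing) the ground truth scores 1. Symmetric; exact on integer
#' boxes.
#'
#' @param roiT,roiG \code{\link{BoundingBox}} objects (tracker result and
#'   ground truth).
#' @return overlap rate in [0, 1].
#' @examples
#' overlapRate(BoundingBox(0, 0, 10, 10), BoundingBox(5, 0, 10, 10))  # 0.5
#' @export
overlapRate <- function(roiT, roiG) {
  if (boxArea(roiT) <= 0 || boxArea(roiG) <= 0) stop("zero-area box")
  ix <- max(0, min(roiT@x + roiT@w, roiG@x + roiG@w) - max(roiT@x, roiG@x))
  iy <- max(0, min(roiT@y + roiT@h, roiG@y + roiG@h) - max(roiT@y, roiG@y))
  # exact on integer boxes; the clamp only absorbs floating-point noise
  # of fractional (tracker-produced) boxes
  min(1, (ix * iy) / min(boxArea(roiT), boxArea(roiG)))
}

#' Per-frame tracking correctness
#'
#' A frame is correct when its overlap rate is strictly larger than the
#' 0.5 threshold.
#'
#' @param orValue overlap rate(s) in [0, 1].
#' @param threshold correctness threshold (strict).
#' @return logical vector.
#' @export
frameCorrect <- function(orValue, threshold = 0.5) {
  stopifnot(all(orValue >= 0 & orValue <= 1))
  orValue > threshold
}

#' Tracking precision
#'
#' Exact ratio of correct frames to total frames.
#'
#' @param correct logical vector of per-frame correctness.
#' @return precision in [0, 1].
#' @export
trackingPrecision <- function(correct) {
  if (!length(correct)) stop("empty correctness list")
  sum(correct) / length(correct)
}

#' Evaluate a trajectory against ground truth
#'
#' Overlap rates are computed where both prediction and truth are present.
#' Absence handling (the overlap rate is undefined for a missing box):
#' absent prediction on an absent-truth frame counts correct, any
#' present/absent mismatch counts incorrect.
#'
#' @param trajectory list of per-frame \code{\link{BoundingBox}} or
#'   \code{NULL} (absent).
#' @param groundTruth list of the same length.
#' @return a \code{\link{TrackingEvaluation}}.
#' @export
evaluateTracking <- function(trajectory, groundTruth) {
  if (length(trajectory) != length(groundTruth))
    stop("trajectory and ground truth lengths differ")
  n <- length(trajectory)
  ors <- rep(NA_real_, n)
  correct <- logical(n)
  for (t in seq_len(n)) {
    p <- trajectory[[t]]; g <- groundTruth[[t]]
    if (is.null(p) && is.null(g)) {
      correct[t] <- TRUE
    } else if (is.null(p) || is.null(g)) {
      correct[t] <- FALSE
    } else {
      ors[t] <- overlapRate(p, g)
      correct[t] <- frameCorrect(ors[t])
    }
  }
  new("TrackingEvaluation", overlap = ors, correct = correct,
      precision = trackingPrecision(correct))
}

#' Run the full per-frame analysis pipeline
#'
#' Composes the three stages causally: iris detection (recomputed every
#' \code{eyeEvery} frames, the latest successful detection carried forward
#' between recomputations so no future frame is consulted), probe tracking
#' with adaptive TLD, and, when both an eye and a probe are available,
#' tissue extraction ahead of the probe tip and hardness grading. Stage
#' failures are recorded per frame and never abort the run.
#'
#' @param frames list of RGB frames.
#' @param initBox annotated probe \code{\link{BoundingBox}} in frame 1.
#' @param cascade fitted \code{\link{GradingCascade}}.
#' @param eyeConfig \code{\link{rhtConfig}} for the detection stage.
#' @param trackConfig \code{\link{tldConfig}} for the tracking stage.
#' @param eyeEvery recompute the eye detection every this many frames
#'   (1 = per frame).
#' @param roiSize tissue ROI side in pixels.
#' @return a data frame with one row per frame: eye geometry and stage,
#'   probe box and provenance, grade and whether stage 2 of the grading
#'   cascade ran.
#' @export
runPipeline <- function(frames, initBox, cascade, eyeConfig = rhtConfig(),
                        trackConfig = tldConfig(), eyeEvery = 10L,
                        roiSize = 32L) {
  n <- length(frames)
  track <- trackVideo(frames, initBox, trackConfig)
  eye <- NULL; eyeStage <- "none"
  out <- vector("list", n)
  for (t in seq_len(n)) {
    if (t == 1L || (t - 1L) %% eyeEvery == 0L) {
      det <- detectEye(frames[[t]], eyeConfig)
      if (!is.null(det$ellipse)) { eye <- det$ellipse; eyeStage <- det$stage }
    }
    box <- track$trajectory[[t]]
    grade <- NA_integer_; stage2 <- NA
    if (!is.null(eye) && !is.null(box)) {
      g <- tryCatch({
        roi <- extractTissueRoi(frames[[t]], box, eye, roiSize)
        gradeTissue(roi$patch, cascade)
      }, error = function(e) NULL)
      if (!is.null(g)) { grade <- g$grade; stage2 <- g$stage2Invoked }
    }
    out[[t]] <- data.frame(
      frame = t,
      eyeFound = !is.null(eye),
      eyeStage = eyeStage,
      eyeCx = if (is.null(eye)) NA_real_ else eye@cx,
      eyeCy = if (is.null(eye)) NA_real_ else eye@cy,
      eyeA = if (is.null(eye)) NA_real_ else eye@a,
      eyeB = if (is.null(eye)) NA_real_ else eye@b,
      eyeTheta = if (is.null(eye)) NA_real_ else eye@theta,
      probePresent = !is.null(box),
      probeSource = track$source[t],
      probeX = if (is.null(box)) NA_real_ else box@x,
      probeY = if (is.null(box)) NA_real_ else box@y,
      probeW = if (is.null(box)) NA_real_ else box@w,
      probeH = if (is.null(box)) NA_real_ else box@h,
      grade = grade,
      stage2Invoked = stage2)
  }
  do.call(rbind, out)
}
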