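#' Configuration for the randomized Hough transform detectors
#'
#' @param nSamples number of point groups to sample.
#' @param minPairDistance minimum Euclidean distance (pixels) allowed
#'   between any two points of a sampled group; 0 disables the constraint
#'   (standard randomized Hough sampling). \code{NULL} lets
#'   \code{\link{detectEye}} choose 5 percent of the image diagonal.
#' @param bins number of accumulator bins per parameter dimension.
#' @param voteThreshold minimum accumulator peak count required in every
#'   dimension; \code{NULL} selects \code{max(10, 0.02 * nSamples)}.
#' @param maxAttempts rejection-sampling attempts per group before the
#'   group is skipped.
#' @param inlierTol distance (pixels) within which an edge point counts as
#'   an inlier of a candidate shape.
#' @param minInlierFraction minimum inlier fraction for the circle stage to
#'   report success.
#' @param seed optional RNG seed making a detection run reproducible.
#' @return a list of class \code{"rhtConfig"}.
#' @export
rhtConfig <- function(nSamples = 1000L, minPairDistance = NULL, bins = 64L,
                      voteThreshold = NULL, maxAttempts = 30L, inlierTol = 2,
                      minInlierFraction = 0.5, seed = NULL) {
  stopifnot(nSamples >= 1L, is.null(minPairDistance) || minPairDistance >= 0)
  if (is.null(voteThreshold)) voteThreshold <- max(10, round(0.02 * nSamples))
  structure(list(nSamples = as.integer(nSamples),
                 minPairDistance = minPairDistance, bins = as.integer(bins),
                 voteThreshold = voteThreshold,
                 maxAttempts = as.integer(maxAttempts), inlierTol = inlierTol,
                 minInlierFraction = minInlierFraction, seed = seed),
            class = "rhtConfig")
}

#' Distance-constrained group sampling
#'
#' Draws \code{k} distinct points such that every pairwise distance is at
#' least \code{minPairDistance}; nearby point pairs produce ill-conditioned
#' minimal fits, so excluding them suppresses noise votes. Rejection
#' sampling is bounded: after \code{maxAttempts} failed draws the function
#' returns \code{NULL}.
#'
#' @param points an n x 2 matrix of candidate points.
#' @param k group size.
#' @param minPairDistance minimum pairwise distance in pixels (0 reduces to
#'   unconstrained sampling of distinct points).
#' @param maxAttempts bound on rejection-sampling attempts.
#' @return a k x 2 matrix (with attribute \code{"indices"}) or \code{NULL}.
#' @export
sampleGroup <- function(points, k, minPairDistance = 0, maxAttempts = 30L) {
  n <- nrow(points)
  if (k > n) stop("cannot sample ", k, " points from ", n)
  for (a in seq_len(maxAttempts)) {
    idx <- sample.int(n, k)
    g <- points[idx, , drop = FALSE]
    if (minPairDistance > 0) {
      if (min(dist(g)) < minPairDistance) next
    }
    attr(g, "indices") <- idx
    return(g)
  }
  NULL
}

# Peak of a 1-D accumulator: bins over the central 96% quantile range.
# Returns the peak count plus a membership mask of votes lying in the peak
# bin or its immediate neighbours.
accumulatorPeak <- function(x, bins) {
  rng <- unname(quantile(x, c(0.02, 0.98), names = FALSE))
  if (!all(is.finite(rng)) || diff(rng) < 1e-12) {
    m <- median(x)
    near <- abs(x - m) <= 1e-12 + 1e-9 * abs(m)
    return(list(center = m, count = sum(near), members = near))
  }
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  binw <- breaks[2] - breaks[1]
  inside <- x >= rng[1] & x <= rng[2]
  b <- findInterval(x[inside], breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(b, nbins = bins)
  peak <- which.max(counts)
  center <- (breaks[peak] + breaks[peak + 1L]) / 2
  list(center = center, count = counts[peak],
       members = x >= center - 1.5 * binw & x <= center + 1.5 * binw)
}

# Joint peak vote: votes inside the peak region of (almost) all dimensions;
# their component-wise median is a coherent parameter vector, unlike the
# concatenation of independently quantised bin centers.
jointPeakVote <- function(V, peaks) {
  score <- rowSums(vapply(peaks, `[[`, logical(nrow(V)), "members"))
  for (need in ncol(V):max(2L, ncol(V) - 1L)) {
    sel <- score >= need
    if (sum(sel) >= 3L) return(apply(V[sel, , drop = FALSE], 2, median))
  }
  NULL
}

#' Ellipse detection with the distance-constrained randomized Hough
#' transform
#'
#' Repeatedly samples five-point groups (respecting the pairwise distance
#' constraint), solves the exact conic through each group, keeps only
#' hypotheses classified as ellipses by the conic discriminant, and votes
#' each of the five reduced conic parameters into its own one-dimensional
#' accumulator. When every accumulator peak reaches the vote threshold, a
#' candidate ellipse is assembled from the per-dimension peak bin centers
#' and refined by a least-squares conic fit over edge points within
#' \code{inlierTol} pixels of the candidate boundary.
#'
#' @param points n x 2 matrix of edge points (n >= 5).
#' @param config an \code{\link{rhtConfig}}.
#' @param diagnostics return accumulator diagnostics alongside the result.
#' @return an \code{\link{Ellipse}} or \code{NULL}; with
#'   \code{diagnostics = TRUE}, a list with elements \code{ellipse},
#'   \code{peakCounts}, \code{nVotes}, \code{nInliers}.
#' @export
detectEllipseRht <- function(points, config = rhtConfig(), diagnostics = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 5L) stop("ellipse detection needs at least five points")
  run <- function() {
    minD <- if (is.null(config$minPairDistance)) 0 else config$minPairDistance
    rngX <- range(points[, 1]); rngY <- range(points[, 2])
    span <- sqrt(diff(rngX)^2 + diff(rngY)^2)
    maxAxis <- 0.75 * span
    V <- matrix(NA_real_, config$nSamples, 5)
    nv <- 0L
    for (i in seq_len(config$nSamples)) {
      g <- sampleGroup(points, 5L, minD, config$maxAttempts)
      if (is.null(g)) next
      k <- fitConic5(g)
      if (is.null(k) || !conicIsEllipse(k)) next
      el <- conicToEllipse(k)
      if (is.null(el)) next
      if (el@a > maxAxis || el@b < 2) next
      if (el@cx < rngX[1] - 0.2 * span || el@cx > rngX[2] + 0.2 * span ||
          el@cy < rngY[1] - 0.2 * span || el@cy > rngY[2] + 0.2 * span) next
      nv <- nv + 1L
      V[nv, ] <- c(k@b, k@c, k@d, k@e, k@f)
    }
    out <- list(ellipse = NULL, peakCounts = rep(0, 5), nVotes = nv, nInliers = 0L)
    if (nv < config$voteThreshold) return(out)
    V <- V[seq_len(nv), , drop = FALSE]
    peaks <- lapply(seq_len(5), function(j) accumulatorPeak(V[, j], config$bins))
    out$peakCounts <- vapply(peaks, `[[`, numeric(1), "count")
    if (min(out$peakCounts) < config$voteThreshold) return(out)
    jp <- jointPeakVote(V, peaks)
    if (is.null(jp)) return(out)
    cand <- conicToEllipse(ConicParams(jp[1], jp[2], jp[3], jp[4], jp[5]))
    if (is.null(cand)) return(out)
    for (pass in 1:2) {
      d <- ellipseBoundaryDistance(cand, points)
      inl <- points[d <= config$inlierTol, , drop = FALSE]
      out$nInliers <- nrow(inl)
      if (nrow(inl) < max(5L, config$voteThreshold)) return(out)
      kr <- fitConicLS(inl)
      refined <- if (is.null(kr)) NULL else conicToEllipse(kr)
      if (is.null(refined)) break
      cand <- refined
    }
    out$ellipse <- cand
    out
  }
  res <- if (is.null(config$seed)) run() else withSeed(config$seed, run())
  if (diagnostics) res else res$ellipse
}

#' Circle detection with the distance-constrained randomized Hough
#' transform
#'
#' Three-point analogue of \code{\link{detectEllipseRht}} with
#' one-dimensional accumulators over (cx, cy, r). The circle stage fails
#' (returns \code{NULL}) when an accumulator peak is below the vote
#' threshold or when fewer than \code{minInlierFraction} of the edge points
#' lie within \code{inlierTol} pixels of the candidate circle; the latter
#' rejects genuinely elliptical contours.
#'
#' @inheritParams detectEllipseRht
#' @return a \code{\link{Circle}} or \code{NULL}; with diagnostics, a list
#'   with \code{circle}, \code{peakCounts}, \code{nVotes},
#'   \code{inlierFraction}.
#' @export
detectCircleRht <- function(points, config = rhtConfig(), diagnostics = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("circle detection needs at least three points")
  run <- function() {
    minD <- if (is.null(config$minPairDistance)) 0 else config$minPairDistance
    rngX <- range(points[, 1]); rngY <- range(points[, 2])
    span <- sqrt(diff(rngX)^2 + diff(rngY)^2)
    maxR <- 0.75 * span
    V <- matrix(NA_real_, config$nSamples, 3)
    nv <- 0L
    for (i in seq_len(config$nSamples)) {
      g <- sampleGroup(points, 3L, minD, config$maxAttempts)
      if (is.null(g)) next
      ci <- fitCircle3(g)
      if (is.null(ci)) next
      if (ci@r > maxR || ci@r < 3) next
      if (ci@cx < rngX[1] - 0.2 * span || ci@cx > rngX[2] + 0.2 * span ||
          ci@cy < rngY[1] - 0.2 * span || ci@cy > rngY[2] + 0.2 * span) next
      nv <- nv + 1L
      V[nv, ] <- c(ci@cx, ci@cy, ci@r)
    }
    out <- list(circle = NULL, peakCounts = rep(0, 3), nVotes = nv,
                inlierFraction = 0)
    if (nv < config$voteThreshold) return(out)
    V <- V[seq_len(nv), , drop = FALSE]
    peaks <- lapply(seq_len(3), function(j) accumulatorPeak(V[, j], config$bins))
    out$peakCounts <- vapply(peaks, `[[`, numeric(1), "count")
    if (min(out$peakCounts) < config$voteThreshold) return(out)
    jp <- jointPeakVote(V, peaks)
    if (is.null(jp) || jp[3] <= 0) return(out)
    cand <- Circle(jp[1], jp[2], jp[3])
    for (pass in 1:2) {
      d <- abs(sqrt((points[, 1] - cand@cx)^2 + (points[, 2] - cand@cy)^2) - cand@r)
      inl <- points[d <= config$inlierTol, , drop = FALSE]
      out$inlierFraction <- nrow(inl) / nrow(points)
      if (out$inlierFraction < config$minInlierFraction) return(out)
      refined <- fitCircleLS(inl)
      if (is.null(refined)) break
      cand <- refined
    }
    d <- abs(sqrt((points[, 1] - cand@cx)^2 + (points[, 2] - cand@cy)^2) - cand@r)
    out$inlierFraction <- mean(d <= config$inlierTol)
    if (out$inlierFraction < config$minInlierFraction) return(out)
    out$circle <- cand
    out
  }
  res <- if (is.null(config$seed)) run() else withSeed(config$seed, run())
  if (diagnostics) res else res$circle
}

#' Locate the iris in a frame
#'
#' Runs edge preprocessing, then the circle-stage randomized Hough
#' transform; circle detection is attempted first because it is much
#' cheaper, and only when it fails does the ellipse stage run (the iris
#' contour deforms towards an ellipse during surgery). The returned stage
#' flag records which detector produced the result.
#'
#' @param frame grayscale matrix or RGB array.
#' @param config an \code{\link{rhtConfig}}; a \code{NULL}
#'   \code{minPairDistance} is resolved to 5 percent of the image diagonal.
#' @param minComponentSize passed to \code{\link{preprocessFrame}}.
#' @return a list with \code{ellipse} (an \code{\link{Ellipse}} or
#'   \code{NULL}), \code{stage} (\code{"circle"}, \code{"ellipse"} or
#'   \code{"none"}), and \code{nEdgePoints}.
#' @export
detectEye <- function(frame, config = rhtConfig(), minComponentSize = 20L) {
  if (is.null(config$minPairDistance)) {
    d <- sqrt(frameWidth(frame)^2 + frameHeight(frame)^2)
    config$minPairDistance <- 0.05 * d
  }
  pts <- preprocessFrame(frame, minComponentSize = minComponentSize)
  if (nrow(pts) >= 3L) {
    circ <- detectCircleRht(pts, config)
    if (!is.null(circ)) {
      return(list(ellipse = as(circ, "Ellipse"), stage = "circle",
                  nEdgePoints = nrow(pts)))
    }
  }
  if (nrow(pts) >= 5L) {
    el <- detectEllipseRht(pts, config)
    if (!is.null(el)) {
      return(list(ellipse = el, stage = "ellipse", nEdgePoints = nrow(pts)))
    }
  }
  list(ellipse = NULL, stage = "none", nEdgePoints = nrow(pts))
}

#' Anatomical correctness of an iris detection
#'
#' A detection is correct when the detected ellipse encircles the true iris
#' and is itself encircled by the limbus (the boundary between iris and
#' sclera): both containments are checked on a dense boundary sampling.
#'
#' @param detected,irisGT,limbusGT \code{\link{Ellipse}} objects: the
#'   detection, the true iris and the limbus.
#' @param nBoundary boundary points per containment check (>= 360).
#' @param tolPx containment slack in pixels, absorbing the pixel
#'   quantisation of the edge points a detection is fitted to.
#' @return logical.
#' @export
detectionCorrect <- function(detected, irisGT, limbusGT, nBoundary = 360L,
                             tolPx = 0.5) {
  nBoundary <- max(360L, as.integer(nBoundary))
  grow <- function(e) Ellipse(e@cx, e@cy, e@a + tolPx, e@b + tolPx, e@theta)
  all(ellipseContains(grow(detected), ellipseBoundary(irisGT, nBoundary))) &&
    all(ellipseContains(grow(limbusGT), ellipseBoundary(detected, nBoundary)))
}
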