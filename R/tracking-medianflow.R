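#' Median Flow frame-to-frame tracker
#'
#' Tracks a grid of points inside the box from the previous frame to the
#' current one with a pyramidal Lucas-Kanade tracker, tracks the results
#' backward again, and discards points whose forward-backward error is
#' above the median or whose local appearance correlation is below the
#' median. The box is translated by the median displacement of the
#' surviving points and rescaled by the median ratio of their pairwise
#' distances. Tracking fails (returns \code{NULL}) when too few points
#' survive or the median forward-backward error of the survivors exceeds
#' \code{fbFailThreshold}.
#'
#' @param prevFrame,frame consecutive frames (grayscale matrices or RGB
#'   arrays).
#' @param box current \code{\link{BoundingBox}} in \code{prevFrame}.
#' @param gridSize points are laid out on a gridSize x gridSize lattice
#'   inside the box (10 percent inset); the low-contrast half of the
#'   lattice is dropped, since the box of a thin instrument also contains
#'   background whose motion must not dominate the median.
#' @param halfWin Lucas-Kanade window half-size in pixels.
#' @param levels pyramid levels.
#' @param maxIter,eps Lucas-Kanade iteration controls.
#' @param fbFailThreshold failure threshold (pixels) on the median
#'   forward-backward error of surviving points.
#' @param minPoints minimum surviving points.
#' @return the predicted \code{\link{BoundingBox}} with attributes
#'   \code{"medianFB"} and \code{"nPoints"}, or \code{NULL} on failure.
#' @export
medianFlow <- function(prevFrame, frame, box, gridSize = 7L, halfWin = 4L,
                       levels = 3L, maxIter = 20L, eps = 0.01,
                       fbFailThreshold = 10, minPoints = 8L) {
  prevGray <- asGray(prevFrame); gray <- asGray(frame)
  h <- nrow(prevGray); w <- ncol(prevGray)
  if (box@x < 0 || box@y < 0 || box@x + box@w > w || box@y + box@h > h)
    stop("box lies outside the frame")
  xs <- seq(box@x + 0.1 * box@w, box@x + 0.9 * box@w, length.out = gridSize)
  ys <- seq(box@y + 0.1 * box@h, box@y + 0.9 * box@h, length.out = gridSize)
  pts <- as.matrix(expand.grid(x = xs, y = ys))
  offs <- as.matrix(expand.grid(dx = -2:2, dy = -2:2))
  contrast <- vapply(seq_len(nrow(pts)), function(i) {
    v <- bilinearSample(prevGray, pts[i, 1] + offs[, 1], pts[i, 2] + offs[, 2])
    mean(v^2) - mean(v)^2
  }, numeric(1))
  keepContrast <- contrast >= median(contrast)
  highContrast <- contrast >= quantile(contrast, 2 / 3)[[1]]
  highContrast <- highContrast[keepContrast]
  pts <- pts[keepContrast, , drop = FALSE]

  prevPyr <- buildPyramid(prevGray, levels)
  nextPyr <- buildPyramid(gray, levels)
  fwd <- .lkTrackPyr(prevPyr, nextPyr, pts, halfWin, maxIter, eps)
  bwd <- .lkTrackPyr(nextPyr, prevPyr, fwd$points, halfWin, maxIter, eps)
  valid <- fwd$status & bwd$status
  if (sum(valid) < minPoints) return(NULL)
  fb <- sqrt(rowSums((bwd$points - pts)^2))
  ncc <- patchCorrelation(prevGray, gray, pts, fwd$points, halfWin = 2L)
  medFB <- median(fb[valid]); medNCC <- median(ncc[valid])
  keep <- valid & fb <= medFB & ncc >= medNCC
  if (sum(keep) < minPoints / 2) return(NULL)
  if (median(fb[keep]) > fbFailThreshold) return(NULL)

  # the displacement median prefers the highest-contrast points (the
  # instrument), falling back to all survivors if none of them survived
  dispKeep <- if (any(keep & highContrast)) keep & highContrast else keep
  d <- fwd$points[dispKeep, , drop = FALSE] - pts[dispKeep, , drop = FALSE]
  dx <- median(d[, 1]); dy <- median(d[, 2])
  s <- 1
  kp <- which(keep)
  if (length(kp) >= 3L) {
    prs <- utils::combn(kp, 2L)
    d0 <- sqrt((pts[prs[1, ], 1] - pts[prs[2, ], 1])^2 +
                 (pts[prs[1, ], 2] - pts[prs[2, ], 2])^2)
    d1 <- sqrt((fwd$points[prs[1, ], 1] - fwd$points[prs[2, ], 1])^2 +
                 (fwd$points[prs[1, ], 2] - fwd$points[prs[2, ], 2])^2)
    ok <- d0 > 1e-9 & is.finite(d1)
    if (any(ok)) s <- median(d1[ok] / d0[ok])
  }
  cx <- box@x + box@w / 2 + dx
  cy <- box@y + box@h / 2 + dy
  nw <- box@w * s; nh <- box@h * s
  out <- BoundingBox(cx - nw / 2, cy - nh / 2, nw, nh)
  attr(out, "medianFB") <- median(fb[keep])
  attr(out, "nPoints") <- sum(keep)
  out
}

# Normalised cross-correlation of small patches around point pairs.
patchCorrelation <- function(grayA, grayB, ptsA, ptsB, halfWin = 2L) {
  offs <- as.matrix(expand.grid(dx = -halfWin:halfWin, dy = -halfWin:halfWin))
  vapply(seq_len(nrow(ptsA)), function(i) {
    a <- bilinearSample(grayA, ptsA[i, 1] + offs[, 1], ptsA[i, 2] + offs[, 2])
    b <- bilinearSample(grayB, ptsB[i, 1] + offs[, 1], ptsB[i, 2] + offs[, 2])
    a <- a - mean(a); b <- b - mean(b)
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den < 1e-12) 0 else sum(a * b) / den
  }, numeric(1))
}

# Resample the (possibly fractional) box region to a size x size gray patch.
extractPatch <- function(gray, box, size = 15L) {
  xs <- seq(box@x, box@x + box@w - 1, length.out = size)
  ys <- seq(box@y, box@y + box@h - 1, length.out = size)
  g <- expand.grid(y = ys, x = xs)
  matrix(bilinearSample(gray, g$x, g$y), size, size)
}
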