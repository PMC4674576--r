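#' Extract the tissue patch ahead of the probe tip
#'
#' The tissue to be graded sits at the working end of the
#' phacoemulsification probe. The tip is taken as the midpoint of the box
#' edge nearest the eye center; the region of interest is a square of side
#' \code{roiSize} centered half a side beyond the tip towards the eye
#' center, shifted inward as needed so it stays inside the eye, and
#' resampled to the normalised 32 x 32 patch used by the classifiers.
#' When the probe box is centered exactly on the eye center the direction
#' is degenerate; the tie is broken deterministically towards -y (the top
#' edge).
#'
#' @param frame RGB frame (h x w x 3 array in [0, 1]).
#' @param probeBox probe \code{\link{BoundingBox}}.
#' @param eye iris \code{\link{Ellipse}}.
#' @param roiSize side of the square region of interest, pixels.
#' @return a list with \code{patch} (32 x 32 x 3), \code{roi} (the source
#'   \code{BoundingBox}) and \code{tip} (the tip point).
#' @export
extractTissueRoi <- function(frame, probeBox, eye, roiSize = 32L) {
  stopifnot(length(dim(frame)) == 3L)
  H <- dim(frame)[1]; W <- dim(frame)[2]
  bc <- boxCenter(probeBox)
  ec <- center(eye)
  edges <- rbind(
    top    = c(bc[1], probeBox@y),
    left   = c(probeBox@x, bc[2]),
    right  = c(probeBox@x + probeBox@w, bc[2]),
    bottom = c(bc[1], probeBox@y + probeBox@h))
  d <- sqrt((edges[, 1] - ec[1])^2 + (edges[, 2] - ec[2])^2)
  tip <- edges[which.min(d), ]  # which.min ties resolve to the first row (-y)
  degenerate <- ec[1] >= probeBox@x && ec[1] <= probeBox@x + probeBox@w &&
    ec[2] >= probeBox@y && ec[2] <= probeBox@y + probeBox@h
  if (degenerate) {
    # eye center inside the box: no outward direction exists; place the
    # ROI adjacent to the top edge (towards -y), deterministically
    tip <- edges["top", ]
    dir <- c(0, -1)
  } else {
    dir <- ec - tip
    nd <- sqrt(sum(dir^2))
    dir <- if (nd < 1e-9) c(0, -1) else dir / nd
  }
  ctr <- tip + dir * roiSize / 2
  # pull the ROI towards the eye center until it sits inside the eye
  for (i in 0:40) {
    corners <- rbind(ctr + c(-1, -1) * roiSize / 2, ctr + c(1, -1) * roiSize / 2,
                     ctr + c(-1, 1) * roiSize / 2, ctr + c(1, 1) * roiSize / 2)
    if (all(ellipseContains(eye, corners, tol = 1e-6))) break
    towards <- ec - ctr
    nt <- sqrt(sum(towards^2))
    if (nt < 1e-9) break
    ctr <- ctr + towards / nt * 2
  }
  x0 <- ctr[1] - roiSize / 2; y0 <- ctr[2] - roiSize / 2
  if (x0 < 0 || y0 < 0 || x0 + roiSize > W || y0 + roiSize > H)
    stop("tissue ROI falls outside the frame")
  if (!all(ellipseContains(eye, rbind(ctr), tol = 1e-6)))
    stop("tissue ROI cannot be placed inside the eye")
  rows <- round(y0) + seq_len(roiSize)
  cols <- round(x0) + seq_len(roiSize)
  sub <- frame[rows, cols, , drop = FALSE]
  patch <- if (roiSize == 32L) sub else resampleBilinear(sub, 32L, 32L)
  list(patch = patch,
       roi = BoundingBox(round(x0), round(y0), roiSize, roiSize),
       tip = tip)
}

#' Color feature vector of a normalised tissue patch
#'
#' Concatenates the per-pixel RGB triples of the 32 x 32 patch (row-major,
#' channel fastest) with the per-cell mean RGB triples of its 8 x 8 grid
#' partition (64 cells of 4 x 4 pixels, row-major); the cell means are
#' exact arithmetic means. Values are on the [0, 1] channel scale, so the
#' full vector has length 3 * (1024 + 64) = 3264.
#'
#' @param patch 32 x 32 x 3 array in [0, 1].
#' @param cellGrid cells per side of the averaging grid.
#' @param meansOnly drop the raw pixel block and keep only the cell means
#'   (length \code{3 * cellGrid^2}).
#' @return numeric feature vector.
#' @export
extractFeatures <- function(patch, cellGrid = 8L, meansOnly = FALSE) {
  d <- dim(patch)
  if (length(d) != 3L || d[1] != 32L || d[2] != 32L || d[3] != 3L)
    stop("patch must be a normalised 32 x 32 x 3 array")
  if (32L %% cellGrid != 0L) stop("cellGrid must divide 32")
  cs <- 32L %/% cellGrid
  A <- kronecker(diag(cellGrid), matrix(1 / cs, cs, 1))  # 32 x cellGrid
  cellMeans <- array(0, c(cellGrid, cellGrid, 3))
  for (ch in 1:3) cellMeans[, , ch] <- t(A) %*% patch[, , ch] %*% A
  meanVec <- as.vector(aperm(cellMeans, c(3, 2, 1)))
  if (meansOnly) return(meanVec)
  pixVec <- as.vector(aperm(patch, c(3, 2, 1)))
  c(pixVec, meanVec)
}

featureMatrix <- function(patches, meansOnly = FALSE) {
  t(vapply(patches, extractFeatures, numeric(if (meansOnly) 192L else 3264L),
           meansOnly = meansOnly))
}

#' Train the cascaded hardness-grading classifier
#'
#' Stage 1 is a binary RBF-SVM separating normal tissue (label 0) from
#' cataract (labels 1-5); stage 2 is a five-class RBF-SVM (one-vs-one
#' voting) over the cataract grades only. Hyperparameters are selected by
#' seeded k-fold cross-validation over a logarithmic grid; to keep the
#' search affordable the CV runs on a per-class subsample
#' (\code{cvPerClass}) and the final models are refitted on the full
#' training set with the selected parameters.
#'
#' @param patches list of 32 x 32 x 3 patches, or a precomputed feature
#'   matrix.
#' @param labels integer labels 0-5; all six classes must be present.
#' @param costs,gammas hyperparameter grids.
#' @param folds cross-validation folds.
#' @param cvPerClass per-class subsample size for the CV search.
#' @param meansOnly use the cell-means-only feature variant.
#' @param seed RNG seed (fold assignment, subsampling).
#' @return a \code{\link{GradingCascade}}.
#' @export
trainCascade <- function(patches, labels, costs = 2^c(-2, 2, 6, 10),
                         gammas = 2^c(-10, -6, -2, 2), folds = 5L,
                         cvPerClass = 100L, meansOnly = FALSE, seed = 1L) {
  labels <- as.integer(labels)
  missing <- setdiff(0:5, unique(labels))
  if (length(missing))
    stop("missing class(es) in training data: ", paste(missing, collapse = ", "))
  X <- if (is.matrix(patches)) patches else featureMatrix(patches, meansOnly)
  stopifnot(nrow(X) == length(labels))

  cvSearch <- function(Xs, ys, seedOffset) {
    withSeed(seed + seedOffset, {
      # per-class subsample for the search
      idx <- unlist(lapply(split(seq_along(ys), ys), function(ii)
        if (length(ii) > cvPerClass) sample(ii, cvPerClass) else ii))
      Xs <- Xs[idx, , drop = FALSE]; ys <- ys[idx]
      fold <- sample(rep_len(seq_len(folds), length(ys)))
      grid <- expand.grid(cost = costs, gamma = gammas)
      acc <- vapply(seq_len(nrow(grid)), function(g) {
        correct <- 0L
        for (k in seq_len(folds)) {
          tr <- fold != k
          if (length(unique(ys[tr])) < 2L) next
          fit <- e1071::svm(Xs[tr, , drop = FALSE], ys[tr],
                            kernel = "radial", cost = grid$cost[g],
                            gamma = grid$gamma[g], scale = FALSE)
          correct <- correct + sum(predict(fit, Xs[!tr, , drop = FALSE]) == ys[!tr])
        }
        correct / length(ys)
      }, numeric(1))
      cbind(grid, accuracy = acc)
    })
  }

  y1 <- factor(ifelse(labels == 0L, "normal", "cataract"),
               levels = c("normal", "cataract"))
  cv1 <- cvSearch(X, y1, 0L)
  best1 <- cv1[which.max(cv1$accuracy), ]
  stage1 <- e1071::svm(X, y1, kernel = "radial", cost = best1$cost,
                       gamma = best1$gamma, scale = FALSE)

  sel <- labels > 0L
  y2 <- factor(labels[sel], levels = 1:5)
  cv2 <- cvSearch(X[sel, , drop = FALSE], y2, 1L)
  best2 <- cv2[which.max(cv2$accuracy), ]
  stage2 <- e1071::svm(X[sel, , drop = FALSE], y2, kernel = "radial",
                       cost = best2$cost, gamma = best2$gamma, scale = FALSE)

  new("GradingCascade", stage1 = stage1, stage2 = stage2,
      cvStage1 = cv1, cvStage2 = cv2,
      featureMode = if (meansOnly) "means" else "full")
}

#' Grade a tissue patch with the cascade
#'
#' Stage 1 decides normal versus cataract; only for cataract is the
#' five-class stage 2 consulted (so a "normal" decision can never be
#' escalated to an energy-releasing grade). The returned record includes a
#' flag showing whether stage 2 ran.
#'
#' @param patch 32 x 32 x 3 array, or a feature vector matching the
#'   cascade's feature mode.
#' @param cascade a fitted \code{\link{GradingCascade}}.
#' @return list with \code{grade} (integer 0-5) and \code{stage2Invoked}.
#' @export
gradeTissue <- function(patch, cascade) {
  if (!is(cascade, "GradingCascade") || is.null(cascade@stage1))
    stop("cascade is not fitted")
  f <- if (is.numeric(patch) && is.null(dim(patch))) {
    matrix(patch, nrow = 1)
  } else {
    matrix(extractFeatures(patch, meansOnly = cascade@featureMode == "means"),
           nrow = 1)
  }
  s1 <- predict(cascade@stage1, f)
  if (s1 == "normal") return(list(grade = 0L, stage2Invoked = FALSE))
  g <- as.integer(as.character(predict(cascade@stage2, f)))
  list(grade = g, stage2Invoked = TRUE)
}

#' Grade many feature vectors at once
#'
#' Vectorised equivalent of \code{\link{gradeTissue}}: stage 1 classifies
#' all rows, and stage 2 is invoked only on the rows stage 1 called
#' cataract, preserving the cascade contract.
#'
#' @param features feature matrix (rows = samples).
#' @param cascade fitted \code{\link{GradingCascade}}.
#' @return data frame with \code{grade} and \code{stage2Invoked}.
#' @export
gradeBatch <- function(features, cascade) {
  s1 <- predict(cascade@stage1, features)
  grade <- integer(nrow(features))
  cataract <- s1 == "cataract"
  if (any(cataract)) {
    g2 <- predict(cascade@stage2, features[cataract, , drop = FALSE])
    grade[cataract] <- as.integer(as.character(g2))
  }
  data.frame(grade = grade, stage2Invoked = as.logical(cataract))
}

#' K-nearest-neighbour grading baseline
#'
#' Majority vote among the k nearest training feature vectors (Euclidean
#' distance); ties are broken in favour of the tied label with the
#' smallest mean neighbour distance.
#'
#' @param trainX training feature matrix (rows = samples).
#' @param trainY integer labels.
#' @param testX feature vector or matrix of query features.
#' @param k number of neighbours (5 by default).
#' @return integer vector of predicted labels.
#' @export
knnBaseline <- function(trainX, trainY, testX, k = 5L) {
  if (!nrow(trainX)) stop("empty training set")
  stopifnot(k <= nrow(trainX), nrow(trainX) == length(trainY))
  if (is.null(dim(testX))) testX <- matrix(testX, nrow = 1)
  trainNorm <- rowSums(trainX^2)
  out <- integer(nrow(testX))
  chunk <- 200L
  for (lo in seq(1L, nrow(testX), by = chunk)) {
    hi <- min(lo + chunk - 1L, nrow(testX))
    G <- trainX %*% t(testX[lo:hi, , drop = FALSE])
    for (i in lo:hi) {
      d2 <- trainNorm - 2 * G[, i - lo + 1L] + sum(testX[i, ]^2)
      nb <- order(d2)[seq_len(k)]
      votes <- table(trainY[nb])
      top <- names(votes)[votes == max(votes)]
      if (length(top) > 1L) {
        md <- vapply(top, function(lb)
          mean(sqrt(pmax(0, d2[nb][trainY[nb] == as.integer(lb)]))), numeric(1))
        top <- top[which.min(md)]
      }
      out[i] <- as.integer(top)
    }
  }
  out
}
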