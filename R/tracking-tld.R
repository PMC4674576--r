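#' Configuration for the adaptive Tracking-Learning-Detection tracker
#'
#' Defaults follow the conventional TLD lineage: a 10-classifier fern
#' ensemble with 13 pixel comparisons each, 15 x 15 normalised patches, a
#' nearest-neighbour threshold of 0.6 and a 10 px median forward-backward
#' failure threshold. \code{adaptiveFraction = 0.2} marks one fifth of the
#' base classifiers adaptive; setting it to 0 reproduces the baseline
#' tracker exactly.
#'
#' @param nFerns,nPairsPerFern ensemble geometry.
#' @param fernThreshold ensemble decision threshold as a fraction of
#'   \code{nFerns} (posterior sum must exceed
#'   \code{fernThreshold * nFerns}).
#' @param patchSize side of the normalised gray patch.
#' @param varianceRatio windows with gray variance below
#'   \code{varianceRatio} times the initial patch variance are rejected.
#' @param nnThreshold nearest-neighbour relative-similarity threshold.
#' @param trackerAcceptSim minimum relative similarity for the Median Flow
#'   box to be accepted as a valid output.
#' @param reliabilitySim minimum conservative similarity for P-N learning
#'   to run on a frame.
#' @param fbFailThreshold,mfGridSize,lkHalfWin,lkLevels,lkMaxIter,lkEps
#'   Median Flow / Lucas-Kanade controls (see \code{\link{medianFlow}}).
#' @param scaleSteps powers of 1.2 defining the scan-scale pyramid.
#' @param strideFrac sliding-window stride as a fraction of the window's
#'   smaller side.
#' @param maxCandidates ensemble survivors passed to the NN stage.
#' @param adaptiveFraction fraction of base classifiers marked adaptive.
#' @param pOverlap,nOverlap overlap-rate limits of the P and N experts.
#' @param maxModelPatches cap on stored exemplars per class.
#' @param maxNegPerFrame cap on negative fern updates per frame.
#' @param seed RNG seed (fern pairs, adaptive subset, initial negatives).
#' @return a list of class \code{"tldConfig"}.
#' @export
tldConfig <- function(nFerns = 10L, nPairsPerFern = 13L, fernThreshold = 0.5,
                      patchSize = 15L, varianceRatio = 0.5, nnThreshold = 0.6,
                      trackerAcceptSim = 0.55, reliabilitySim = 0.6,
                      fbFailThreshold = 10, mfGridSize = 7L, lkHalfWin = 4L,
                      lkLevels = 3L, lkMaxIter = 20L, lkEps = 0.01,
                      scaleSteps = -2:2, strideFrac = 0.1,
                      maxCandidates = 25L, adaptiveFraction = 0.2,
                      pOverlap = 0.6, nOverlap = 0.2,
                      maxModelPatches = 100L, maxNegPerFrame = 20L, seed = 1L) {
  structure(as.list(environment()), class = "tldConfig")
}

# Overlap rate (intersection over the smaller area) of grid rows vs a box.
boxOverlapVec <- function(grid, box) {
  ix <- pmax(0, pmin(grid[, 1] + grid[, 3], box@x + box@w) - pmax(grid[, 1], box@x))
  iy <- pmax(0, pmin(grid[, 2] + grid[, 4], box@y + box@h) - pmax(grid[, 2], box@y))
  ix * iy / pmin(grid[, 3] * grid[, 4], box@w * box@h)
}

clampBoxToFrame <- function(box, W, H) {
  if (is.null(box)) return(NULL)
  w <- min(box@w, W); h <- min(box@h, H)
  x <- min(max(box@x, 0), W - w)
  y <- min(max(box@y, 0), H - h)
  BoundingBox(x, y, w, h)
}

# Sliding-window grid over a scale pyramid; the exact initial box is added
# as its own scale so self-detection is always representable.
buildScanGrid <- function(W, H, box, cfg) {
  dims <- lapply(cfg$scaleSteps, function(s)
    c(max(6L, round(box@w * 1.2^s)), max(6L, round(box@h * 1.2^s))))
  dims <- c(dims, list(c(round(box@w), round(box@h))))
  dims <- unique(lapply(dims, as.integer))
  scales <- list(); rows <- list()
  si <- 0L
  for (d in dims) {
    wS <- d[1]; hS <- d[2]
    if (wS > W || hS > H) next
    si <- si + 1L
    scales[[si]] <- c(w = wS, h = hS)
    st <- max(2L, round(cfg$strideFrac * min(wS, hS)))
    xs <- seq.int(0L, W - wS, by = st)
    ys <- seq.int(0L, H - hS, by = st)
    g <- expand.grid(x = xs, y = ys)
    rows[[si]] <- cbind(g$x, g$y, wS, hS, si)
  }
  grid <- do.call(rbind, rows)
  # ensure the exact (rounded) init window is present
  ib <- c(round(box@x), round(box@y), round(box@w), round(box@h))
  sIdx <- which(vapply(scales, function(s) s["w"] == ib[3] && s["h"] == ib[4], logical(1)))[1]
  grid <- rbind(grid, c(ib, sIdx))
  list(grid = grid, scales = scales)
}

# Per-scale integer pixel-pair offsets: normalised pair coordinates scaled
# to the window, as linear offsets into the column-major gray vector.
scaleOffsetsFor <- function(pairs, scales, H) {
  lapply(scales, function(s) {
    dx1 <- round(pairs[, "u1"] * (s["w"] - 1L)); dy1 <- round(pairs[, "v1"] * (s["h"] - 1L))
    dx2 <- round(pairs[, "u2"] * (s["w"] - 1L)); dy2 <- round(pairs[, "v2"] * (s["h"] - 1L))
    list(off1 = as.integer(dx1 * H + dy1), off2 = as.integer(dx2 * H + dy2))
  })
}

# Fern codes for windows sharing one scale; first pair = least significant
# bit, matching fernCode().
windowCodesAt <- function(grayVec, H, xs, ys, off, nFerns, nPairs) {
  base <- as.integer(xs) * H + as.integer(ys) + 1L
  codes <- matrix(0L, nFerns, length(base))
  pw2 <- 2L^(seq_len(nPairs) - 1L)
  q <- 0L
  for (f in seq_len(nFerns)) {
    code <- integer(length(base))
    for (j in seq_len(nPairs)) {
      q <- q + 1L
      bit <- grayVec[base + off$off1[q]] > grayVec[base + off$off2[q]]
      code <- code + as.integer(bit) * pw2[j]
    }
    codes[f, ] <- code
  }
  codes
}

windowVariances <- function(gray, grid) {
  ii <- integralImage(gray); ii2 <- integralImage(gray^2)
  n <- grid[, 3] * grid[, 4]
  s1 <- boxSums(ii, grid[, 1], grid[, 2], grid[, 3], grid[, 4])
  s2 <- boxSums(ii2, grid[, 1], grid[, 2], grid[, 3], grid[, 4])
  s2 / n - (s1 / n)^2
}

#' Initialise the TLD tracker from an annotated first frame
#'
#' Builds the scan grid, generates the fern ensemble, records the initial
#' patch variance for the variance gate, trains the ensemble on the
#' annotated box (plus one-pixel shifts) against a seeded sample of
#' far-away windows, and seeds the nearest-neighbour object model.
#'
#' @param frame first frame (grayscale matrix or RGB array).
#' @param box manually annotated probe \code{\link{BoundingBox}}.
#' @param config a \code{\link{tldConfig}}.
#' @return a tracker state list (class \code{"trackState"}) holding the
#'   object model, the fern ensemble and the cumulative P-N counters.
#' @export
tldInit <- function(frame, box, config = tldConfig()) {
  gray <- asGray(frame)
  H <- nrow(gray); W <- ncol(gray)
  if (box@x < 0 || box@y < 0 || box@x + box@w > W || box@y + box@h > H)
    stop("initial box lies outside the frame")
  sg <- buildScanGrid(W, H, box, config)
  ens <- fernEnsemble(config$nFerns, config$nPairsPerFern,
                      threshold = config$fernThreshold * config$nFerns,
                      adaptiveFraction = config$adaptiveFraction,
                      seed = config$seed)
  offs <- scaleOffsetsFor(ens$pairs, sg$scales, H)
  grayVec <- as.vector(gray)

  rows <- round(box@y) + seq_len(round(box@h))
  cols <- round(box@x) + seq_len(round(box@w))
  pix <- gray[rows, cols]
  initVar <- mean(pix^2) - mean(pix)^2
  initPatch <- extractPatch(gray, box, config$patchSize)

  initScale <- sg$grid[nrow(sg$grid), 5]
  shifts <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  px <- pmin(pmax(round(box@x) + shifts[, 1], 0L), W - round(box@w))
  py <- pmin(pmax(round(box@y) + shifts[, 2], 0L), H - round(box@h))
  posCodes <- windowCodesAt(grayVec, H, px, py, offs[[initScale]],
                            ens$nFerns, ens$nPairs)
  for (i in seq_len(ncol(posCodes)))
    ens$P[cbind(seq_len(ens$nFerns), posCodes[, i] + 1L)] <-
      ens$P[cbind(seq_len(ens$nFerns), posCodes[, i] + 1L)] + 1L

  vars <- windowVariances(gray, sg$grid)
  or <- boxOverlapVec(sg$grid, box)
  negPool <- which(vars >= config$varianceRatio * initVar & or < config$nOverlap)
  model <- list(pos = list(initPatch), neg = list(), patchSize = config$patchSize)
  withSeed(config$seed + 1L, {
    if (length(negPool)) {
      take <- negPool[sample.int(length(negPool), min(100L, length(negPool)))]
      for (si in unique(sg$grid[take, 5])) {
        sel <- take[sg$grid[take, 5] == si]
        codes <- windowCodesAt(grayVec, H, sg$grid[sel, 1], sg$grid[sel, 2],
                               offs[[si]], ens$nFerns, ens$nPairs)
        for (i in seq_len(ncol(codes)))
          ens$N[cbind(seq_len(ens$nFerns), codes[, i] + 1L)] <-
            ens$N[cbind(seq_len(ens$nFerns), codes[, i] + 1L)] + 1L
      }
      for (i in head(take, 10L)) {
        b <- BoundingBox(sg$grid[i, 1], sg$grid[i, 2], sg$grid[i, 3], sg$grid[i, 4])
        model$neg <- c(model$neg, list(extractPatch(gray, b, config$patchSize)))
      }
    }
  })
  if (!length(model$neg)) {
    # degenerate scene: synthesise one flat negative so the NN stage is defined
    model$neg <- list(matrix(mean(gray), config$patchSize, config$patchSize))
  }
  ens <- adaptivePosteriorUpdate(ens, 0L, 0L)
  state <- list(config = config, W = W, H = H, grid = sg$grid,
                scales = sg$scales, offsets = offs, ensemble = ens,
                model = model, initVar = initVar, nPos = 0L, nTot = 0L,
                lastScan = NULL)
  class(state) <- "trackState"
  state
}

#' Run the cascaded TLD detector on one frame
#'
#' Every scan window passes the variance gate, then the fern ensemble, and
#' the highest-scoring survivors are reconfirmed by the nearest-neighbour
#' classifier. Deterministic given the state.
#'
#' @param frame frame to scan.
#' @param state tracker state from \code{\link{tldInit}}.
#' @return list with \code{candidates} (data frame of boxes with fern sums
#'   and similarities) and the updated \code{state} (scan cache used by
#'   P-N learning).
#' @export
tldDetect <- function(frame, state) {
  cfg <- state$config
  gray <- asGray(frame)
  grayVec <- as.vector(gray)
  ens <- state$ensemble
  grid <- state$grid
  vars <- windowVariances(gray, grid)
  varPass <- vars >= cfg$varianceRatio * state$initVar
  fernSum <- rep(NA_real_, nrow(grid))
  codesStore <- vector("list", length(state$scales))
  for (si in seq_along(state$scales)) {
    idx <- which(varPass & grid[, 5] == si)
    if (!length(idx)) next
    codes <- windowCodesAt(grayVec, state$H, grid[idx, 1], grid[idx, 2],
                           state$offsets[[si]], ens$nFerns, ens$nPairs)
    vals <- ens$posterior[cbind(rep(seq_len(ens$nFerns), ncol(codes)),
                                as.vector(codes) + 1L)]
    fernSum[idx] <- colSums(matrix(vals, ens$nFerns, ncol(codes)))
    codesStore[[si]] <- list(idx = idx, codes = codes)
  }
  surv <- which(!is.na(fernSum) & fernSum > ens$threshold)
  surv <- surv[order(fernSum[surv], decreasing = TRUE)]
  surv <- head(surv, cfg$maxCandidates)
  cand <- data.frame(x = numeric(0), y = numeric(0), w = numeric(0),
                     h = numeric(0), fernSum = numeric(0),
                     relSim = numeric(0), consSim = numeric(0))
  for (i in surv) {
    b <- BoundingBox(grid[i, 1], grid[i, 2], grid[i, 3], grid[i, 4])
    nn <- nnConfirm(extractPatch(gray, b, cfg$patchSize), state$model,
                    cfg$nnThreshold)
    if (nn$relative > cfg$nnThreshold) {
      cand <- rbind(cand, data.frame(x = grid[i, 1], y = grid[i, 2],
                                     w = grid[i, 3], h = grid[i, 4],
                                     fernSum = fernSum[i],
                                     relSim = nn$relative,
                                     consSim = nn$conservative))
    }
  }
  state$lastScan <- list(varPass = varPass, fernSum = fernSum,
                         codesStore = codesStore)
  list(candidates = cand, state = state)
}

# Greedy overlap clustering of detector candidates.
clusterCandidates <- function(cand) {
  if (!nrow(cand)) return(cand[0, ])
  ord <- order(cand$relSim, decreasing = TRUE)
  cand <- cand[ord, ]
  assigned <- rep(0L, nrow(cand))
  nc <- 0L
  for (i in seq_len(nrow(cand))) {
    if (assigned[i]) next
    nc <- nc + 1L
    assigned[i] <- nc
    bi <- BoundingBox(cand$x[i], cand$y[i], cand$w[i], cand$h[i])
    if (i < nrow(cand)) {
      rest <- (i + 1L):nrow(cand)
      todo <- rest[assigned[rest] == 0L]
      if (length(todo)) {
        or <- boxOverlapVec(as.matrix(cand[todo, c("x", "y", "w", "h")]), bi)
        assigned[todo[or > 0.5]] <- nc
      }
    }
  }
  out <- do.call(rbind, lapply(seq_len(nc), function(k) {
    m <- cand[assigned == k, , drop = FALSE]
    wgt <- m$relSim / sum(m$relSim)
    data.frame(x = sum(m$x * wgt), y = sum(m$y * wgt),
               w = sum(m$w * wgt), h = sum(m$h * wgt),
               relSim = max(m$relSim), consSim = max(m$consSim), n = nrow(m))
  }))
  out
}

#' Combine tracker and detector outputs
#'
#' The Median Flow box is accepted when its appearance still matches the
#' object model; agreeing detections (high overlap rate) refine it by a
#' confidence-weighted average, while a single distant, clearly more
#' confident detection cluster re-initialises the tracker. When the
#' tracker has failed, one confident detection cluster restarts tracking;
#' with neither, the object is declared absent (an explicit state, never a
#' degenerate box).
#'
#' @param frame current frame.
#' @param trackerBox Median Flow output (\code{NULL} on failure).
#' @param candidates detector candidates from \code{\link{tldDetect}}.
#' @param state tracker state.
#' @return list with \code{box} (\code{\link{BoundingBox}} or \code{NULL}),
#'   \code{source} (\code{"tracker"}, \code{"combined"}, \code{"detector"}
#'   or \code{"absent"}) and \code{sim}.
#' @export
tldIntegrate <- function(frame, trackerBox, candidates, state) {
  cfg <- state$config
  gray <- asGray(frame)
  tb <- clampBoxToFrame(trackerBox, state$W, state$H)
  tSim <- 0
  tValid <- FALSE
  if (!is.null(tb)) {
    tSim <- nnConfirm(extractPatch(gray, tb, cfg$patchSize), state$model,
                      cfg$nnThreshold)$relative
    tValid <- tSim >= cfg$trackerAcceptSim
  }
  cl <- clusterCandidates(candidates)
  if (tValid) {
    if (nrow(cl)) {
      orT <- boxOverlapVec(as.matrix(cl[, c("x", "y", "w", "h")]), tb)
      far <- which(orT < 0.5 & cl$relSim > tSim + 0.05)
      if (length(far)) {
        far <- far[which.max(cl$relSim[far])]
        b <- BoundingBox(cl$x[far], cl$y[far], cl$w[far], cl$h[far])
        return(list(box = clampBoxToFrame(b, state$W, state$H),
                    source = "detector", sim = cl$relSim[far]))
      }
      close <- which(orT > 0.5)
      if (length(close)) {
        wgt <- c(10 * tSim, cl$relSim[close])
        wgt <- wgt / sum(wgt)
        xs <- c(tb@x, cl$x[close]); ys <- c(tb@y, cl$y[close])
        ws <- c(tb@w, cl$w[close]); hs <- c(tb@h, cl$h[close])
        b <- BoundingBox(sum(xs * wgt), sum(ys * wgt), sum(ws * wgt), sum(hs * wgt))
        return(list(box = clampBoxToFrame(b, state$W, state$H),
                    source = "combined", sim = tSim))
      }
    }
    return(list(box = tb, source = "tracker", sim = tSim))
  }
  if (nrow(cl)) {
    # re-detection after tracker failure is gated on the conservative
    # similarity so a drifted background cannot restart the track
    best <- which.max(cl$relSim)
    if (cl$relSim[best] > cfg$nnThreshold && cl$consSim[best] > cfg$nnThreshold) {
      b <- BoundingBox(cl$x[best], cl$y[best], cl$w[best], cl$h[best])
      return(list(box = clampBoxToFrame(b, state$W, state$H),
                  source = "detector", sim = cl$relSim[best]))
    }
  }
  list(box = NULL, source = "absent", sim = 0)
}

#' P-N learning update
#'
#' Runs only when the final location is reliable (conservative similarity
#' of its patch above \code{reliabilitySim}). The P-expert promotes scan
#' windows that overlap the final box but were labelled negative by the
#' detector into positive training samples; the N-expert demotes
#' non-overlapping windows the ensemble labelled positive into negatives.
#' Fern counts, the object model and the cumulative positive/total sample
#' counters are updated, then the adaptive posterior entries are refreshed
#' with the new ratio.
#'
#' @param state tracker state (must hold the scan cache of the current
#'   frame, i.e. \code{\link{tldDetect}} ran on this frame).
#' @param frame current frame.
#' @param finalBox integrated output box.
#' @return the updated state.
#' @export
pnUpdate <- function(state, frame, finalBox) {
  cfg <- state$config
  if (is.null(state$lastScan)) return(state)
  gray <- asGray(frame)
  grayVec <- as.vector(gray)
  nn <- nnConfirm(extractPatch(gray, finalBox, cfg$patchSize), state$model,
                  cfg$nnThreshold)
  if (nn$conservative < cfg$reliabilitySim) return(state)
  ens <- state$ensemble
  grid <- state$grid
  fernSum <- state$lastScan$fernSum
  detPos <- !is.na(fernSum) & fernSum > ens$threshold
  or <- boxOverlapVec(grid, finalBox)

  codesFor <- function(idx) {
    out <- matrix(0L, ens$nFerns, length(idx))
    for (si in unique(grid[idx, 5])) {
      sel <- which(grid[idx, 5] == si)
      out[, sel] <- windowCodesAt(grayVec, state$H, grid[idx[sel], 1],
                                  grid[idx[sel], 2], state$offsets[[si]],
                                  ens$nFerns, ens$nPairs)
    }
    out
  }
  bump <- function(M, codes) {
    for (i in seq_len(ncol(codes))) {
      ij <- cbind(seq_len(ens$nFerns), codes[, i] + 1L)
      M[ij] <- M[ij] + 1L
    }
    M
  }

  pIdx <- which(or > cfg$pOverlap & !detPos)
  pIdx <- head(pIdx[order(or[pIdx], decreasing = TRUE)], 10L)
  if (length(pIdx)) {
    ens$P <- bump(ens$P, codesFor(pIdx))
    if (length(state$model$pos) < cfg$maxModelPatches) {
      i <- pIdx[1]
      b <- BoundingBox(grid[i, 1], grid[i, 2], grid[i, 3], grid[i, 4])
      state$model$pos <- c(state$model$pos,
                           list(extractPatch(gray, b, cfg$patchSize)))
    }
  }
  if (nn$relative < cfg$nnThreshold + 0.05 &&
      length(state$model$pos) < cfg$maxModelPatches) {
    state$model$pos <- c(state$model$pos,
                         list(extractPatch(gray, finalBox, cfg$patchSize)))
  }

  nIdx <- which(or < cfg$nOverlap & detPos)
  nIdx <- head(nIdx[order(fernSum[nIdx], decreasing = TRUE)], cfg$maxNegPerFrame)
  if (length(nIdx)) {
    ens$N <- bump(ens$N, codesFor(nIdx))
    nAdd <- head(nIdx, 3L)
    for (i in nAdd) {
      if (length(state$model$neg) >= cfg$maxModelPatches) break
      b <- BoundingBox(grid[i, 1], grid[i, 2], grid[i, 3], grid[i, 4])
      state$model$neg <- c(state$model$neg,
                           list(extractPatch(gray, b, cfg$patchSize)))
    }
  }

  state$nPos <- state$nPos + length(pIdx)
  state$nTot <- state$nTot + length(pIdx) + length(nIdx)
  state$ensemble <- adaptivePosteriorUpdate(ens, state$nPos, state$nTot)
  state
}

#' Track the probe through a video
#'
#' Full adaptive TLD loop: Median Flow prediction, cascaded detection,
#' tracker/detector integration, P-N learning and the adaptive posterior
#' refresh, frame by frame. The probe location in frame 1 is supplied
#' (annotated) and tracking proceeds from there; absence is an explicit
#' per-frame state.
#'
#' @param frames list of frames (grayscale matrices or RGB arrays).
#' @param initBox annotated \code{\link{BoundingBox}} in frame 1.
#' @param config a \code{\link{tldConfig}}.
#' @return list with \code{trajectory} (per-frame \code{BoundingBox} or
#'   \code{NULL}), \code{source} (per-frame provenance flags) and the
#'   final \code{state}.
#' @export
trackVideo <- function(frames, initBox, config = tldConfig()) {
  n <- length(frames)
  stopifnot(n >= 1L)
  grays <- lapply(frames, asGray)
  state <- tldInit(grays[[1]], initBox, config)
  traj <- vector("list", n)
  src <- character(n)
  traj[[1]] <- initBox; src[1] <- "init"
  box <- initBox
  for (t in seq_len(n)[-1]) {
    tb <- NULL
    if (!is.null(box)) {
      tb <- tryCatch(
        medianFlow(grays[[t - 1L]], grays[[t]], box,
                   gridSize = config$mfGridSize, halfWin = config$lkHalfWin,
                   levels = config$lkLevels, maxIter = config$lkMaxIter,
                   eps = config$lkEps,
                   fbFailThreshold = config$fbFailThreshold),
        error = function(e) NULL)
    }
    det <- tldDetect(grays[[t]], state)
    state <- det$state
    integ <- tldIntegrate(grays[[t]], tb, det$candidates, state)
    box <- integ$box
    if (!is.null(box)) state <- pnUpdate(state, grays[[t]], box)
    traj[t] <- list(box)  # keeps an explicit NULL slot for absent frames
    src[t] <- integ$source
  }
  list(trajectory = traj, source = src, state = state)
}
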