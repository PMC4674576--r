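#' Binary fern code of a patch
#'
#' Each feature of a base classifier is a comparison between two pixels of
#' the normalised patch; bit \code{i} is 1 iff the first pixel of pair
#' \code{i} is strictly brighter than the second. The first pair is the
#' least significant bit, so a patch of k pairs maps to a code in
#' \code{[0, 2^k - 1]}. A constant patch yields code 0.
#'
#' @param patch numeric matrix (grayscale patch).
#' @param pairs k x 4 integer matrix of 0-based pixel coordinates
#'   \code{(x1, y1, x2, y2)} into the patch.
#' @return integer code.
#' @export
fernCode <- function(patch, pairs) {
  pairs <- as.matrix(pairs)
  h <- nrow(patch); w <- ncol(patch)
  if (any(pairs[, c(1, 3)] < 0 | pairs[, c(1, 3)] >= w) ||
      any(pairs[, c(2, 4)] < 0 | pairs[, c(2, 4)] >= h))
    stop("pixel pair index out of patch range")
  v1 <- patch[cbind(pairs[, 2] + 1, pairs[, 1] + 1)]
  v2 <- patch[cbind(pairs[, 4] + 1, pairs[, 3] + 1)]
  bits <- v1 > v2
  sum(as.integer(bits) * 2L^(seq_along(bits) - 1L))
}

#' Create a random-fern ensemble
#'
#' Pixel pairs are generated once (seeded) in normalised \code{[0, 1)}
#' coordinates and stay fixed at runtime; they are instantiated per scan
#' scale by scaling to the window size. A random subset of
#' \code{ceiling(adaptiveFraction * nFerns)} base classifiers is marked
#' adaptive: their posterior entries never observed in training follow the
#' running positive-sample ratio of P-N learning (0.5 before any sample)
#' instead of defaulting to 0.
#'
#' @param nFerns number of base classifiers.
#' @param nPairs pixel comparisons per base classifier.
#' @param threshold decision threshold on the posterior sum (absolute).
#' @param adaptiveFraction fraction of base classifiers marked adaptive
#'   (0 disables the adaptive rule, giving the baseline ensemble).
#' @param seed RNG seed for pair generation and adaptive subset selection.
#' @return a list of class \code{"fernEnsemble"} with elements
#'   \code{pairs} (normalised coordinates), count matrices \code{P} and
#'   \code{N}, the \code{posterior} table, \code{adaptiveIdx} and
#'   \code{threshold}.
#' @export
fernEnsemble <- function(nFerns = 10L, nPairs = 13L, threshold = 0.5 * nFerns,
                         adaptiveFraction = 0.2, seed = 1L) {
  stopifnot(nFerns >= 1L, nPairs >= 1L, nPairs <= 16L)
  withSeed(seed, {
    pairs <- matrix(runif(nFerns * nPairs * 4L), ncol = 4L)
    colnames(pairs) <- c("u1", "v1", "u2", "v2")
    nAdaptive <- if (adaptiveFraction > 0) ceiling(adaptiveFraction * nFerns) else 0L
    adaptiveIdx <- if (nAdaptive > 0) sort(sample.int(nFerns, nAdaptive)) else integer(0)
    nCodes <- 2L^nPairs
    ens <- list(nFerns = as.integer(nFerns), nPairs = as.integer(nPairs),
                pairs = pairs,
                P = matrix(0L, nFerns, nCodes), N = matrix(0L, nFerns, nCodes),
                posterior = matrix(0, nFerns, nCodes),
                adaptiveIdx = adaptiveIdx, threshold = threshold)
    class(ens) <- "fernEnsemble"
    adaptivePosteriorUpdate(ens, 0L, 0L)
  })
}

#' Posterior sum of a fern ensemble
#'
#' @param codes integer vector, one fern code per base classifier.
#' @param ensemble a \code{\link{fernEnsemble}}.
#' @return list with \code{posteriorSum} and logical \code{label}
#'   (positive iff the sum exceeds the ensemble threshold).
#' @export
ensembleClassify <- function(codes, ensemble) {
  stopifnot(length(codes) == ensemble$nFerns)
  s <- sum(ensemble$posterior[cbind(seq_len(ensemble$nFerns), codes + 1L)])
  list(posteriorSum = s, label = s > ensemble$threshold)
}

#' Adaptive posterior refresh
#'
#' Recomputes the posterior table from the training counts. Observed
#' entries carry their evidence-based posterior \code{P / (P + N)};
#' unobserved entries are 0 for ordinary base classifiers but, for the
#' adaptive subset, follow the cumulative positive-sample ratio
#' \code{nPositive / nTotal} produced by P-N learning (0.5 before any
#' sample), so long-unseen features no longer force the ensemble towards
#' the negative label.
#'
#' @param ensemble a \code{\link{fernEnsemble}}.
#' @param nPositive,nTotal cumulative P-N learning sample counts.
#' @return the ensemble with an updated \code{posterior} table.
#' @export
adaptivePosteriorUpdate <- function(ensemble, nPositive, nTotal) {
  seen <- ensemble$P + ensemble$N > 0L
  post <- matrix(0, ensemble$nFerns, ncol(ensemble$P))
  post[seen] <- ensemble$P[seen] / (ensemble$P[seen] + ensemble$N[seen])
  if (length(ensemble$adaptiveIdx)) {
    ratio <- if (nTotal > 0) nPositive / nTotal else 0.5
    adUnseen <- !seen[ensemble$adaptiveIdx, , drop = FALSE]
    block <- post[ensemble$adaptiveIdx, , drop = FALSE]
    block[adUnseen] <- ratio
    post[ensemble$adaptiveIdx, ] <- block
  }
  ensemble$posterior <- post
  ensemble
}

#' Gray-value variance gate
#'
#' Scanning windows whose gray-value variance is below half (by default)
#' of the variance of the patch selected for tracking cannot contain the
#' probe and are rejected before the ensemble stage.
#'
#' @param patch numeric matrix (grayscale patch).
#' @param initVariance variance of the initial tracked patch.
#' @param ratio rejection ratio (reject iff \code{var < ratio * initVariance}).
#' @return logical: \code{TRUE} to accept, \code{FALSE} to reject.
#' @export
varianceFilter <- function(patch, initVariance, ratio = 0.5) {
  stopifnot(initVariance >= 0)
  v <- mean(patch^2) - mean(patch)^2
  v >= ratio * initVariance
}

#' Nearest-neighbour reconfirmation
#'
#' Patch similarity is normalised cross-correlation mapped to \code{[0, 1]};
#' with \code{d+ = 1 - S+} and \code{d- = 1 - S-} the distances to the
#' nearest positive and negative exemplar, the relative similarity is
#' \code{d- / (d- + d+)} (1 when the patch coincides with a stored
#' positive, 0 when it coincides with a stored negative, 0.5 in the
#' symmetric case). Conservative similarity restricts the positive set to
#' its earliest 50 percent, so recently added (possibly contaminated)
#' exemplars cannot vouch for a model update.
#'
#' @param patch grayscale patch (same size as the model exemplars).
#' @param model an object model as produced by \code{\link{tldInit}}
#'   (list with \code{pos} and \code{neg} patch lists).
#' @param threshold label threshold on the relative similarity.
#' @return list with \code{relative}, \code{conservative} and logical
#'   \code{label}.
#' @export
nnConfirm <- function(patch, model, threshold = 0.6) {
  if (!length(model$pos) || !length(model$neg))
    stop("object model needs at least one positive and one negative patch")
  sims <- function(set) vapply(set, function(q) patchSimilarity(patch, q), numeric(1))
  sPos <- sims(model$pos)
  dN <- 1 - max(sims(model$neg))
  dP <- 1 - max(sPos)
  nEarly <- ceiling(length(sPos) / 2)
  dPcons <- 1 - max(sPos[seq_len(nEarly)])
  rel <- if (dN + dP < 1e-12) 0.5 else dN / (dN + dP)
  cons <- if (dN + dPcons < 1e-12) 0.5 else dN / (dN + dPcons)
  list(relative = rel, conservative = cons, label = rel > threshold)
}

# NCC mapped to [0,1].
patchSimilarity <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  ncc <- if (den < 1e-12) 0 else sum(a * b) / den
  (ncc + 1) / 2
}
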