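#' Default Emery-Little tissue colors
#'
#' Mean RGB triples (0-255 scale) verbalising the clinical color
#' descriptions of the six hardness classes: normal tissue (label 0), then
#' grades I-V from transparent/non-nuclear through yellow, dark yellow,
#' brown/amber to dark brown or black.
#'
#' @return a 6 x 3 numeric matrix, rows named "0".."5".
#' @export
defaultTissueColors <- function() {
  m <- rbind(
    "0" = c(200, 160, 160),  # normal: pinkish tissue
    "1" = c(235, 235, 235),  # very soft: transparent / non-nuclear
    "2" = c(230, 220, 140),  # soft: yellow or yellow-white
    "3" = c(190, 150,  40),  # medium: dark yellow
    "4" = c(150, 100,  40),  # hard: brown or amber
    "5" = c( 70,  50,  30))  # extremely hard: dark brown or black
  colnames(m) <- c("r", "g", "b")
  m
}

#' Specification of a synthetic eye edge image
#'
#' Describes a binary edge image containing the contour of an iris ellipse
#' plus uniformly scattered noise points, together with the concentric
#' limbus ellipse that bounds a correct detection. The generator is a pure
#' function of this spec (seed included).
#'
#' @param imageSize \code{c(width, height)} in pixels.
#' @param iris ground-truth iris \code{\link{Ellipse}}.
#' @param limbus limbus \code{\link{Ellipse}}; must strictly contain the
#'   iris. Defaults to the iris scaled by 1.3.
#' @param nContourPoints number of distinct contour pixels to emit.
#' @param noiseFraction fraction in \code{[0, 1)} of the final point set
#'   that is uniform noise.
#' @param seed RNG seed.
#' @return a list of class \code{"eyeImageSpec"}.
#' @export
eyeImageSpec <- function(imageSize = c(256, 256), iris,
                         limbus = NULL, nContourPoints = 200L,
                         noiseFraction = 0, seed = 1L) {
  if (is.null(limbus)) limbus <- Ellipse(iris@cx, iris@cy, 1.3 * iris@a,
                                         1.3 * iris@b, iris@theta)
  spec <- list(imageSize = as.integer(imageSize), iris = iris, limbus = limbus,
               nContourPoints = as.integer(nContourPoints),
               noiseFraction = noiseFraction, seed = as.integer(seed))
  class(spec) <- "eyeImageSpec"
  validateEyeImageSpec(spec)
  spec
}

validateEyeImageSpec <- function(spec) {
  w <- spec$imageSize[1]; h <- spec$imageSize[2]
  if (spec$noiseFraction < 0 || spec$noiseFraction >= 1)
    stop("noiseFraction must lie in [0, 1)")
  if (spec$nContourPoints < 1L) stop("nContourPoints must be positive")
  strictlyInside <- function(inner, outer) {
    all(ellipseContains(outer, ellipseBoundary(inner, 360L), tol = -1e-9))
  }
  bd <- rbind(ellipseBoundary(spec$iris, 360L), ellipseBoundary(spec$limbus, 360L))
  if (any(bd[, 1] <= 0 | bd[, 1] >= w - 1 | bd[, 2] <= 0 | bd[, 2] >= h - 1))
    stop("iris and limbus must lie strictly inside the image bounds")
  if (!strictlyInside(spec$iris, spec$limbus))
    stop("iris must lie strictly inside the limbus")
  invisible(spec)
}

#' Generate a synthetic binary eye edge image
#'
#' Emits exactly \code{nContourPoints} distinct pixels on the iris contour
#' (parametric samples rounded to the pixel grid, deduplicated) plus
#' \code{ceiling(f / (1 - f) * nContourPoints)} uniformly scattered noise
#' pixels, where \code{f} is the noise fraction; ground truth accompanies
#' the data.
#'
#' @param spec an \code{\link{eyeImageSpec}}.
#' @return a list with \code{image} (binary h x w matrix), \code{points}
#'   (all emitted points, contour first), \code{contourPoints},
#'   \code{noisePoints}, \code{iris}, \code{limbus}.
#' @export
generateEyeImage <- function(spec) {
  stopifnot(inherits(spec, "eyeImageSpec"))
  validateEyeImageSpec(spec)
  w <- spec$imageSize[1]; h <- spec$imageSize[2]
  n <- spec$nContourPoints
  withSeed(spec$seed, {
    pts <- matrix(numeric(0), 0, 2)
    seen <- character(0)
    tries <- 0L
    while (nrow(pts) < n) {
      tries <- tries + 1L
      if (tries > 60L) stop("iris contour cannot supply ", n, " distinct pixels")
      cand <- round(ellipseBoundary(spec$iris, 4L * n)[sample.int(4L * n), ])
      for (i in seq_len(nrow(cand))) {
        key <- paste(cand[i, 1], cand[i, 2])
        if (!key %in% seen) {
          seen <- c(seen, key)
          pts <- rbind(pts, cand[i, ])
          if (nrow(pts) == n) break
        }
      }
    }
    nNoise <- ceiling(spec$noiseFraction / (1 - spec$noiseFraction) * n)
    noise <- matrix(numeric(0), 0, 2)
    if (nNoise > 0) {
      idx <- sample.int(w * h, nNoise) - 1L
      noise <- cbind(idx %% w, idx %/% w)
    }
    all <- rbind(pts, noise)
    img <- matrix(0, h, w)
    img[cbind(all[, 2] + 1, all[, 1] + 1)] <- 1
    colnames(all) <- colnames(pts) <- c("x", "y")
    if (nrow(noise)) colnames(noise) <- c("x", "y")
    list(image = img, points = all, contourPoints = pts, noisePoints = noise,
         iris = spec$iris, limbus = spec$limbus)
  })
}

#' Specification of a synthetic probe video
#'
#' Describes a short video of a rigid, needle-like probe moving over a
#' drifting textured background, optionally inside an iris disc filled with
#' tissue of a known hardness grade. The background texture is a sum of
#' low-frequency sinusoids whose phase advances every frame by
#' \code{driftRate}, reproducing gradual appearance change without
#' object-like distractors; the probe texture is rigid and constant.
#'
#' @param frameSize \code{c(width, height)} pixels.
#' @param nFrames number of frames.
#' @param probeSize \code{c(width, height)} of the probe bounding box.
#' @param trajectory nFrames x 2 matrix of per-frame top-left positions;
#'   defaults to a gentle linear sweep that keeps the box in frame.
#' @param driftRate per-frame phase advance (radians) of the background
#'   texture; 0 freezes the background.
#' @param backgroundAmplitude peak amplitude of the background texture
#'   (intensity units on [0,1]).
#' @param occlusionFrames integer frame indices (1-based) on which the probe
#'   is not rendered; ground truth is marked absent there.
#' @param probeShape \code{"needle"} renders a thin diagonal instrument
#'   inside the bounding box (so the box also contains background, the
#'   situation that confuses the baseline tracker);
#'   \code{"rect"} fills the whole box with rigid texture.
#' @param iris optional \code{\link{Ellipse}}: when given, the inside is
#'   filled with the tissue color of \code{tissueGrade} and the outside with
#'   a sclera tone.
#' @param tissueGrade Emery-Little label 0-5 selecting the tissue color from
#'   \code{colors} (used only with \code{iris}).
#' @param colors 6 x 3 matrix of grade colors, 0-255 scale.
#' @param seed RNG seed.
#' @return a list of class \code{"probeVideoSpec"}.
#' @export
probeVideoSpec <- function(frameSize = c(160L, 120L), nFrames = 100L,
                           probeSize = c(36L, 14L), trajectory = NULL,
                           driftRate = 0, backgroundAmplitude = 0.12,
                           occlusionFrames = integer(0), iris = NULL,
                           tissueGrade = 3L, colors = defaultTissueColors(),
                           probeShape = c("needle", "rect"), seed = 1L) {
  probeShape <- match.arg(probeShape)
  frameSize <- as.integer(frameSize); probeSize <- as.integer(probeSize)
  if (is.null(trajectory)) {
    x0 <- round(frameSize[1] * 0.15); y0 <- round(frameSize[2] * 0.3)
    xmax <- frameSize[1] - probeSize[1] - 2L
    ymax <- frameSize[2] - probeSize[2] - 2L
    t <- seq_len(nFrames) - 1L
    trajectory <- cbind(pmin(x0 + 0.4 * t, xmax),
                        pmin(y0 + 0.15 * t, ymax))
  }
  trajectory <- matrix(as.numeric(trajectory), ncol = 2)
  if (nrow(trajectory) == 0L) stop("trajectory must not be empty")
  if (nrow(trajectory) != nFrames)
    stop("trajectory must have one row per frame")
  onscreen <- setdiff(seq_len(nFrames), occlusionFrames)
  if (any(trajectory[onscreen, 1] < 0 | trajectory[onscreen, 2] < 0 |
          trajectory[onscreen, 1] + probeSize[1] > frameSize[1] |
          trajectory[onscreen, 2] + probeSize[2] > frameSize[2]))
    stop("trajectory leaves the frame on a non-occlusion frame")
  spec <- list(frameSize = frameSize, nFrames = as.integer(nFrames),
               probeSize = probeSize, trajectory = trajectory,
               driftRate = driftRate, backgroundAmplitude = backgroundAmplitude,
               occlusionFrames = as.integer(occlusionFrames), iris = iris,
               tissueGrade = as.integer(tissueGrade), colors = colors,
               probeShape = probeShape, seed = as.integer(seed))
  class(spec) <- "probeVideoSpec"
  spec
}

# Rigid probe appearance: a slightly diagonal bright metallic needle with a
# rounded tip, plus fixed speckle. Returns list(texture matrix, mask).
probeAppearance <- function(pw, ph, shape = "needle") {
  if (shape == "rect") {
    speckle <- matrix(runif(ph * pw, -0.25, 0.25), ph, pw)
    xs <- matrix(rep(seq_len(pw) - 1L, each = ph), ph, pw)
    tex <- clamp01(0.55 + 0.25 * sin(xs / 3) + speckle)
    return(list(texture = tex, mask = matrix(TRUE, ph, pw)))
  }
  xs <- matrix(rep(seq_len(pw) - 1L, each = ph), ph, pw)
  ys <- matrix(rep(seq_len(ph) - 1L, pw), ph, pw)
  # needle axis from (0, 0.7h) to (w-1, 0.3h)
  y0 <- 0.7 * (ph - 1); y1 <- 0.3 * (ph - 1)
  yc <- y0 + (y1 - y0) * xs / (pw - 1)
  halfWidth <- 0.22 * ph
  mask <- abs(ys - yc) <= halfWidth
  tip <- (xs - (pw - 2))^2 + (ys - y1)^2 <= (0.45 * ph)^2
  mask <- mask | tip
  # metallic glint: strong speckle over a shaded cylinder profile
  speckle <- matrix(runif(ph * pw, -0.15, 0.15), ph, pw)
  shading <- 0.7 + 0.25 * cos((ys - yc) / max(halfWidth, 1) * pi / 2)
  tex <- clamp01(shading + speckle)
  tex[tip] <- clamp01(0.3 + speckle[tip])  # darker metal tip
  list(texture = tex, mask = mask)
}

#' Generate a synthetic probe video with ground truth
#'
#' @param spec a \code{\link{probeVideoSpec}}.
#' @return a list with \code{frames} (list of h x w x 3 arrays),
#'   \code{boxes} (list of ground-truth \code{\link{BoundingBox}} or
#'   \code{NULL} on occlusion frames), and \code{grade} (the tissue grade
#'   inside the iris, or \code{NA} when no iris was rendered).
#' @export
generateProbeVideo <- function(spec) {
  stopifnot(inherits(spec, "probeVideoSpec"))
  w <- spec$frameSize[1]; h <- spec$frameSize[2]
  pw <- spec$probeSize[1]; ph <- spec$probeSize[2]
  withSeed(spec$seed, {
    nWaves <- 4L
    fx <- runif(nWaves, 1 / 96, 1 / 28)
    fy <- runif(nWaves, 1 / 96, 1 / 28)
    phase0 <- runif(nWaves, 0, 2 * pi)
    omega <- runif(nWaves, 0.5, 1.5)
    amp <- spec$backgroundAmplitude * (0.5 + runif(nWaves)) / nWaves * 2
    probe <- probeAppearance(pw, ph, spec$probeShape)

    X <- matrix(rep(seq_len(w) - 1L, each = h), h, w)
    Y <- matrix(rep(seq_len(h) - 1L, w), h, w)
    phaseMaps <- lapply(seq_len(nWaves), function(k)
      2 * pi * (fx[k] * X + fy[k] * Y) + phase0[k])

    base <- array(0, c(h, w, 3))
    if (is.null(spec$iris)) {
      bg <- c(0.45, 0.40, 0.36)
      for (ch in 1:3) base[, , ch] <- bg[ch]
      irisMask <- matrix(TRUE, h, w)
    } else {
      tissue <- spec$colors[spec$tissueGrade + 1L, ] / 255
      sclera <- c(0.92, 0.90, 0.88)
      irisMask <- matrix(ellipseContains(spec$iris, cbind(as.vector(X), as.vector(Y))), h, w)
      for (ch in 1:3) base[, , ch] <- ifelse(irisMask, tissue[ch], sclera[ch])
    }
    # with an iris the drifting texture lives on the tissue inside it (at
    # reduced amplitude so the color stays gradable) while the white
    # sclera is nearly featureless; without one the whole background
    # drifts at full amplitude
    ampMask <- if (is.null(spec$iris)) {
      matrix(1, h, w)
    } else {
      ifelse(irisMask, 0.5, 0.15)
    }

    frames <- vector("list", spec$nFrames)
    boxes <- vector("list", spec$nFrames)
    for (t in seq_len(spec$nFrames)) {
      field <- matrix(0, h, w)
      for (k in seq_len(nWaves))
        field <- field + amp[k] * sin(phaseMaps[[k]] + (t - 1L) * spec$driftRate * omega[k])
      field <- field * ampMask
      fr <- base
      for (ch in 1:3) fr[, , ch] <- clamp01(base[, , ch] + field)
      if (!(t %in% spec$occlusionFrames)) {
        px <- round(spec$trajectory[t, 1]); py <- round(spec$trajectory[t, 2])
        rows <- py + seq_len(ph); cols <- px + seq_len(pw)
        sub <- probe$mask
        for (ch in 1:3) {
          block <- fr[rows, cols, ch]
          block[sub] <- probe$texture[sub] * c(0.95, 0.97, 1.0)[ch]
          fr[rows, cols, ch] <- block
        }
        boxes[[t]] <- BoundingBox(px, py, pw, ph)
      }  # occlusion frames keep their preallocated NULL (absent)
      frames[[t]] <- fr
    }
    list(frames = frames, boxes = boxes,
         grade = if (is.null(spec$iris)) NA_integer_ else spec$tissueGrade)
  })
}

#' Tissue color model for patch generation
#'
#' @param means 6 x 3 matrix of per-grade mean RGB triples (0-255); rows
#'   are labels 0-5 and must be pairwise distinct.
#' @param noiseSd per-channel Gaussian noise standard deviation, 0-255
#'   scale.
#' @param seed RNG seed.
#' @return a list of class \code{"tissueColorModel"}.
#' @export
tissueColorModel <- function(means = defaultTissueColors(), noiseSd = 10,
                             seed = 1L) {
  means <- as.matrix(means)
  if (nrow(means) != 6L || ncol(means) != 3L)
    stop("means must be a 6 x 3 matrix (labels 0-5)")
  if (anyDuplicated(means)) stop("grade mean colors must be pairwise distinct")
  structure(list(means = means, noiseSd = noiseSd, seed = as.integer(seed)),
            class = "tissueColorModel")
}

#' Generate labeled synthetic tissue patches
#'
#' Each patch is 32 x 32 RGB: the grade's mean color plus independent
#' per-pixel, per-channel Gaussian noise, clipped to the valid channel
#' range.
#'
#' @param model a \code{\link{tissueColorModel}}.
#' @param nPerGrade patches per label (>= 1).
#' @return a list with \code{patches} (list of 32 x 32 x 3 arrays in
#'   [0, 1]) and \code{labels} (integer vector over \{0..5\}).
#' @export
generateTissuePatches <- function(model, nPerGrade) {
  stopifnot(inherits(model, "tissueColorModel"), nPerGrade >= 1L)
  withSeed(model$seed, {
    patches <- vector("list", 6L * nPerGrade)
    labels <- integer(6L * nPerGrade)
    i <- 0L
    for (g in 0:5) {
      mu <- model$means[g + 1L, ] / 255
      sd <- model$noiseSd / 255
      for (j in seq_len(nPerGrade)) {
        i <- i + 1L
        p <- array(0, c(32, 32, 3))
        for (ch in 1:3)
          p[, , ch] <- clamp01(mu[ch] + if (sd > 0) rnorm(1024, 0, sd) else 0)
        patches[[i]] <- p
        labels[i] <- g
      }
    }
    list(patches = patches, labels = labels)
  })
}
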