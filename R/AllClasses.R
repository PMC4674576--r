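#' Ellipse in pixel coordinates
#'
#' Geometric ellipse with center \code{(cx, cy)}, semi-axes \code{a >= b > 0}
#' and orientation \code{theta} (radians, major-axis direction, normalised to
#' \code{[0, pi)}). The constructor canonicalises its arguments: axes are
#' swapped (with a 90 degree rotation) when given with \code{a < b}, and
#' \code{theta} is reduced modulo \code{pi}.
#'
#' @slot cx,cy center, pixels (0-based image coordinates).
#' @slot a,b semi-major / semi-minor axis, pixels.
#' @slot theta orientation of the major axis, radians in \code{[0, pi)}.
#' @export
setClass("Ellipse",
  representation(cx = "numeric", cy = "numeric", a = "numeric",
                 b = "numeric", theta = "numeric"))

setValidity("Ellipse", function(object) {
  v <- c(object@cx, object@cy, object@a, object@b, object@theta)
  if (length(v) != 5L || !all(is.finite(v))) return("all slots must be finite scalars")
  if (object@b <= 0 || object@a < object@b) return("need a >= b > 0")
  if (object@theta < 0 || object@theta >= pi) return("theta must lie in [0, pi)")
  TRUE
})

#' @param cx,cy,a,b,theta see slots.
#' @return \code{Ellipse()} returns an \code{Ellipse} object.
#' @rdname Ellipse-class
#' @export
Ellipse <- function(cx, cy, a, b, theta = 0) {
  if (a < b) { tmp <- a; a <- b; b <- tmp; theta <- theta + pi / 2 }
  theta <- theta %% pi
  new("Ellipse", cx = as.numeric(cx), cy = as.numeric(cy),
      a = as.numeric(a), b = as.numeric(b), theta = as.numeric(theta))
}

#' Circle in pixel coordinates
#'
#' @slot cx,cy center, pixels. @slot r radius, pixels (positive).
#' @export
setClass("Circle", representation(cx = "numeric", cy = "numeric", r = "numeric"))

setValidity("Circle", function(object) {
  if (!all(is.finite(c(object@cx, object@cy, object@r)))) return("slots must be finite")
  if (object@r <= 0) return("r must be positive")
  TRUE
})

#' @param cx,cy,r center and radius.
#' @return \code{Circle()} returns a \code{Circle} object.
#' @rdname Circle-class
#' @export
Circle <- function(cx, cy, r) {
  new("Circle", cx = as.numeric(cx), cy = as.numeric(cy), r = as.numeric(r))
}

setAs("Circle", "Ellipse", function(from) {
  Ellipse(from@cx, from@cy, from@r, from@r, 0)
})

#' Reduced conic parameters
#'
#' Coefficients \code{(b, c, d, e, f)} of the conic
#' \deqn{x^2 + 2 b x y + c y^2 + 2 d x + 2 e y + f = 0,}
#' i.e. the general conic normalised so the \code{x^2} coefficient is 1 (the
#' five-parameter vector determined by five points). Under this convention
#' the curve is an ellipse iff the discriminant \code{b^2 - c} is negative.
#'
#' @slot b,c,d,e,f reduced conic coefficients.
#' @export
setClass("ConicParams",
  representation(b = "numeric", c = "numeric", d = "numeric",
                 e = "numeric", f = "numeric"))

setValidity("ConicParams", function(object) {
  if (!all(is.finite(c(object@b, object@c, object@d, object@e, object@f))))
    return("coefficients must be finite")
  TRUE
})

#' @param b,c,d,e,f coefficients.
#' @return \code{ConicParams()} returns a \code{ConicParams} object.
#' @rdname ConicParams-class
#' @export
ConicParams <- function(b, c, d, e, f) {
  new("ConicParams", b = as.numeric(b), c = as.numeric(c),
      d = as.numeric(d), e = as.numeric(e), f = as.numeric(f))
}

#' Axis-aligned bounding box
#'
#' Rectangle with top-left corner \code{(x, y)} (0-based pixels) and positive
#' width/height. Covers the pixel range \code{[x, x + w) x [y, y + h)}.
#'
#' @slot x,y top-left corner. @slot w,h width and height, pixels.
#' @export
setClass("BoundingBox",
  representation(x = "numeric", y = "numeric", w = "numeric", h = "numeric"))

setValidity("BoundingBox", function(object) {
  if (!all(is.finite(c(object@x, object@y, object@w, object@h))))
    return("slots must be finite")
  if (object@w <= 0 || object@h <= 0) return("w and h must be positive")
  TRUE
})

#' @param x,y,w,h geometry; or a length-4 vector passed as \code{x}.
#' @return \code{BoundingBox()} returns a \code{BoundingBox} object.
#' @rdname BoundingBox-class
#' @export
BoundingBox <- function(x, y = NULL, w = NULL, h = NULL) {
  if (is.null(y) && length(x) == 4L) { y <- x[2]; w <- x[3]; h <- x[4]; x <- x[1] }
  new("BoundingBox", x = as.numeric(x), y = as.numeric(y),
      w = as.numeric(w), h = as.numeric(h))
}

#' Cascaded hardness-grading classifier
#'
#' Stage 1 separates normal tissue from cataract; stage 2 (consulted only for
#' cataract) assigns an Emery-Little grade 1-5. Both stages are RBF-kernel
#' support vector machines with cross-validated hyperparameters.
#'
#' @slot stage1,stage2 fitted \pkg{e1071} svm models.
#' @slot cvStage1,cvStage2 cross-validation grids with accuracies.
#' @slot featureMode \code{"full"} (pixels + cell means) or \code{"means"}.
#' @export
setClass("GradingCascade",
  representation(stage1 = "ANY", stage2 = "ANY",
                 cvStage1 = "data.frame", cvStage2 = "data.frame",
                 featureMode = "character"))

#' Tracking evaluation record
#'
#' Per-frame overlap rates (NA when prediction or truth is absent),
#' per-frame correctness and the resulting precision (fraction of correct
#' frames).
#'
#' @slot overlap numeric vector of overlap rates, NA where undefined.
#' @slot correct logical vector of per-frame correctness.
#' @slot precision exact fraction of correct frames.
#' @export
setClass("TrackingEvaluation",
  representation(overlap = "numeric", correct = "logical", precision = "numeric"))

setValidity("TrackingEvaluation", function(object) {
  if (length(object@overlap) != length(object@correct))
    return("overlap and correct must have equal length")
  ok <- is.na(object@overlap) | (object@overlap >= 0 & object@overlap <= 1)
  if (!all(ok)) return("overlap rates must lie in [0, 1]")
  if (length(object@precision) != 1L || object@precision < 0 || object@precision > 1)
    return("precision must be a scalar in [0, 1]")
  TRUE
})

setMethod("show", "Ellipse", function(object) {
  cat(sprintf("Ellipse: center (%.2f, %.2f), axes (%.2f, %.2f), theta %.3f rad\n",
              object@cx, object@cy, object@a, object@b, object@theta))
})

setMethod("show", "Circle", function(object) {
  cat(sprintf("Circle: center (%.2f, %.2f), r %.2f\n", object@cx, object@cy, object@r))
})

setMethod("show", "ConicParams", function(object) {
  cat(sprintf("Conic x^2 + 2bxy + cy^2 + 2dx + 2ey + f: b=%.4g c=%.4g d=%.4g e=%.4g f=%.4g (%s)\n",
              object@b, object@c, object@d, object@e, object@f,
              if (conicIsEllipse(object)) "ellipse" else "not an ellipse"))
})

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox: x=%.2f y=%.2f w=%.2f h=%.2f\n",
              object@x, object@y, object@w, object@h))
})

setMethod("show", "TrackingEvaluation", function(object) {
  cat(sprintf("TrackingEvaluation: %d frames, precision %.4f\n",
              length(object@correct), object@precision))
})

setMethod("show", "GradingCascade", function(object) {
  cat("GradingCascade: stage 1 normal-vs-cataract, stage 2 grades 1-5 (RBF SVM)\n")
  cat(sprintf("  feature mode: %s\n", object@featureMode))
  if (nrow(object@cvStage1))
    cat(sprintf("  stage 1 best CV accuracy: %.4f\n", max(object@cvStage1$accuracy)))
  if (nrow(object@cvStage2))
    cat(sprintf("  stage 2 best CV accuracy: %.4f\n", max(object@cvStage2$accuracy)))
})

#' Accessors for geometric objects
#'
#' @param x an \code{Ellipse}, \code{Circle} or \code{BoundingBox}.
#' @return \code{center} returns \code{c(x, y)}; \code{semiAxes} returns
#'   \code{c(a, b)}; \code{orientation} the angle in radians; \code{boxArea}
#'   the rectangle area; \code{boxVec} the named vector
#'   \code{c(x, y, w, h)}; \code{boxCenter} the rectangle center.
#' @name geometry-accessors
NULL

#' @rdname geometry-accessors
#' @export
setGeneric("center", function(x) standardGeneric("center"))
#' @rdname geometry-accessors
#' @export
setMethod("center", "Ellipse", function(x) c(x@cx, x@cy))
#' @rdname geometry-accessors
#' @export
setMethod("center", "Circle", function(x) c(x@cx, x@cy))

#' @rdname geometry-accessors
#' @export
semiAxes <- function(x) c(x@a, x@b)

#' @rdname geometry-accessors
#' @export
orientation <- function(x) x@theta

#' @rdname geometry-accessors
#' @export
boxArea <- function(x) x@w * x@h

#' @rdname geometry-accessors
#' @export
boxVec <- function(x) c(x = x@x, y = x@y, w = x@w, h = x@h)

#' @rdname geometry-accessors
#' @export
boxCenter <- function(x) c(x@x + x@w / 2, x@y + x@h / 2)

#' @rdname geometry-accessors
#' @export
trackingPrecisionOf <- function(x) x@precision

#' @rdname geometry-accessors
#' @export
overlapRates <- function(x) x@overlap

#' @rdname geometry-accessors
#' @export
frameCorrectness <- function(x) x@correct
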