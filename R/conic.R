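#' Conic / ellipse conversions and minimal-point fits
#'
#' The detection stage represents a hypothesis as the reduced conic
#' \eqn{x^2 + 2bxy + cy^2 + 2dx + 2ey + f = 0}; these helpers convert
#' between that algebraic form and the geometric
#' (center, semi-axes, orientation) form, and solve the minimal fitting
#' problems used by the randomized Hough transform: five points determine a
#' conic, three points a circle.
#'
#' @param e an \code{\link{Ellipse}}.
#' @param k a \code{\link{ConicParams}} object.
#' @return \code{ellipseToConic} returns \code{ConicParams};
#'   \code{conicToEllipse} returns an \code{Ellipse} or \code{NULL} when the
#'   conic is not a real ellipse; \code{conicIsEllipse} a logical.
#' @examples
#' e <- Ellipse(100, 80, 50, 30, 0.3)
#' conicToEllipse(ellipseToConic(e))
#' @name conic-conversions
NULL

#' @rdname conic-conversions
#' @export
ellipseToConic <- function(e) {
  ct <- cos(e@theta); st <- sin(e@theta)
  ia2 <- 1 / e@a^2; ib2 <- 1 / e@b^2
  A <- ct^2 * ia2 + st^2 * ib2
  C <- st^2 * ia2 + ct^2 * ib2
  B <- ct * st * (ia2 - ib2)
  D <- -(A * e@cx + B * e@cy)
  E <- -(B * e@cx + C * e@cy)
  # Q(x) = A x^2 + 2Bxy + Cy^2 + 2Dx + 2Ey + F vanishes on the boundary
  F <- A * e@cx^2 + 2 * B * e@cx * e@cy + C * e@cy^2 - 1
  ConicParams(B / A, C / A, D / A, E / A, F / A)
}

#' @rdname conic-conversions
#' @export
conicIsEllipse <- function(k) {
  is.finite(k@b) && is.finite(k@c) && (k@b^2 - k@c < 0)
}

#' @rdname conic-conversions
#' @export
conicToEllipse <- function(k) {
  A <- 1; B <- k@b; C <- k@c; D <- k@d; E <- k@e; F <- k@f
  det0 <- A * C - B^2
  if (!is.finite(det0) || det0 <= 0) return(NULL)
  cx <- (B * E - C * D) / det0
  cy <- (B * D - A * E) / det0
  F0 <- A * cx^2 + 2 * B * cx * cy + C * cy^2 + 2 * D * cx + 2 * E * cy + F
  if (!is.finite(F0) || F0 >= 0) return(NULL)  # degenerate or imaginary
  tr <- A + C
  disc <- sqrt((A - C)^2 + 4 * B^2)
  l1 <- (tr + disc) / 2  # larger eigenvalue -> minor axis
  l2 <- (tr - disc) / 2  # smaller eigenvalue -> major axis
  if (l2 <= 0) return(NULL)
  a <- sqrt(-F0 / l2)
  b <- sqrt(-F0 / l1)
  theta <- if (abs(B) < 1e-14) {
    if (A <= C) 0 else pi / 2
  } else {
    atan2(l2 - A, B)
  }
  Ellipse(cx, cy, a, b, theta)
}

#' Fit the reduced conic through five points
#'
#' Solves the 5x5 linear system that makes the conic
#' \eqn{x^2 + 2bxy + cy^2 + 2dx + 2ey + f = 0} pass through all five points.
#' Degenerate configurations (collinear or coincident points, or any
#' configuration making the system singular) return \code{NULL}.
#'
#' @param pts a 5x2 matrix of (x, y) coordinates.
#' @return \code{ConicParams} or \code{NULL} when degenerate.
#' @examples
#' e <- Ellipse(100, 80, 50, 30, 0)
#' pts <- ellipseBoundary(e, 5)
#' fitConic5(pts)
#' @export
fitConic5 <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 5L) stop("fitConic5 needs five points")
  if (nrow(pts) != 5L) pts <- pts[1:5, , drop = FALSE]
  if (nrow(unique(pts)) < 5L) return(NULL)
  x <- pts[, 1]; y <- pts[, 2]
  M <- cbind(2 * x * y, y^2, 2 * x, 2 * y, 1)
  rhs <- -x^2
  sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) return(NULL)
  ConicParams(sol[1], sol[2], sol[3], sol[4], sol[5])
}

#' Algebraic residual of points on a conic
#'
#' Evaluates \eqn{x^2 + 2bxy + cy^2 + 2dx + 2ey + f} at each point, scaled by
#' \eqn{1 + x^2 + y^2} so the residual is comparable across image scales.
#'
#' @param k a \code{ConicParams} object.
#' @param pts an n x 2 matrix of points.
#' @return numeric vector of scaled residuals.
#' @export
conicResidual <- function(k, pts) {
  pts <- as.matrix(pts)
  x <- pts[, 1]; y <- pts[, 2]
  raw <- x^2 + 2 * k@b * x * y + k@c * y^2 + 2 * k@d * x + 2 * k@e * y + k@f
  raw / (1 + x^2 + y^2)
}

#' Fit the circle through three points
#'
#' @param pts a 3x2 matrix of (x, y) coordinates.
#' @return a \code{\link{Circle}} or \code{NULL} for collinear/coincident
#'   points.
#' @examples
#' fitCircle3(rbind(c(0, 1), c(1, 0), c(0, -1)))
#' @export
fitCircle3 <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) stop("fitCircle3 needs three points")
  if (nrow(pts) != 3L) pts <- pts[1:3, , drop = FALSE]
  x <- pts[, 1]; y <- pts[, 2]
  M <- cbind(x, y, 1)
  rhs <- -(x^2 + y^2)
  d <- det(M)
  if (!is.finite(d) || abs(d) < 1e-9) return(NULL)
  sol <- solve(M, rhs)
  cx <- -sol[1] / 2; cy <- -sol[2] / 2
  r2 <- cx^2 + cy^2 - sol[3]
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  Circle(cx, cy, sqrt(r2))
}

# Least-squares conic refinement with the x^2 coefficient pinned to 1
# (same parametrisation as fitConic5, overdetermined).
fitConicLS <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 5L) return(NULL)
  x <- pts[, 1]; y <- pts[, 2]
  M <- cbind(2 * x * y, y^2, 2 * x, 2 * y, 1)
  sol <- tryCatch(qr.solve(M, -x^2), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) return(NULL)
  ConicParams(sol[1], sol[2], sol[3], sol[4], sol[5])
}

# Kasa least-squares circle fit.
fitCircleLS <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) return(NULL)
  x <- pts[, 1]; y <- pts[, 2]
  M <- cbind(x, y, 1)
  sol <- tryCatch(qr.solve(M, -(x^2 + y^2)), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) return(NULL)
  cx <- -sol[1] / 2; cy <- -sol[2] / 2
  r2 <- cx^2 + cy^2 - sol[3]
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  Circle(cx, cy, sqrt(r2))
}

#' Points on an ellipse boundary
#'
#' @param e an \code{\link{Ellipse}}.
#' @param n number of boundary points (uniform in parametric angle).
#' @return an n x 2 matrix of (x, y) coordinates.
#' @export
ellipseBoundary <- function(e, n = 360L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(e@theta); st <- sin(e@theta)
  px <- e@a * cos(t); py <- e@b * sin(t)
  cbind(x = e@cx + ct * px - st * py, y = e@cy + st * px + ct * py)
}

#' Point-in-ellipse test
#'
#' @param e an \code{\link{Ellipse}}.
#' @param pts an n x 2 matrix of points.
#' @param tol tolerance on the canonical quadratic form (boundary points
#'   evaluate to exactly 1; positive \code{tol} accepts "on the boundary"
#'   up to rounding).
#' @return logical vector: point inside or on the ellipse.
#' @export
ellipseContains <- function(e, pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  dx <- pts[, 1] - e@cx; dy <- pts[, 2] - e@cy
  ct <- cos(e@theta); st <- sin(e@theta)
  u <- (dx * ct + dy * st) / e@a
  v <- (-dx * st + dy * ct) / e@b
  u^2 + v^2 <= 1 + tol
}

# Approximate unsigned distance from points to an ellipse boundary via a
# dense boundary sampling (adequate at the +-2 px scale used for inliers).
ellipseBoundaryDistance <- function(e, pts, nBoundary = 720L) {
  pts <- as.matrix(pts)
  bd <- ellipseBoundary(e, nBoundary)
  # squared distances: |p|^2 + |b|^2 - 2 p.b via cross-product matrix
  d2 <- outer(rowSums(pts^2), rowSums(bd^2), "+") - 2 * pts %*% t(bd)
  sqrt(pmax(0, apply(d2, 1, min)))
}
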