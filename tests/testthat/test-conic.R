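test_that("ellipse <-> conic round trip is exact to 1e-6", {
  set.seed(42)
  for (i in 1:50) {
    e <- Ellipse(runif(1, 20, 200), runif(1, 20, 200),
                 runif(1, 20, 80), runif(1, 5, 20), runif(1, 0, pi))
    e2 <- conicToEllipse(ellipseToConic(e))
    expect_lt(abs(e2@cx - e@cx), 1e-6)
    expect_lt(abs(e2@cy - e@cy), 1e-6)
    expect_lt(abs(e2@a - e@a), 1e-6)
    expect_lt(abs(e2@b - e@b), 1e-6)
    expect_lt(min(abs(e2@theta - e@theta), pi - abs(e2@theta - e@theta)), 1e-6)
  }
})

test_that("five-point conic fit passes through its points and matches the SVD oracle", {
  set.seed(7)
  for (i in 1:40) {
    e <- Ellipse(runif(1, 60, 200), runif(1, 60, 200),
                 runif(1, 30, 70), runif(1, 15, 30), runif(1, 0, pi))
    t5 <- sort(runif(5, 0, 2 * pi))
    ct <- cos(e@theta); st <- sin(e@theta)
    px <- e@a * cos(t5); py <- e@b * sin(t5)
    pts <- cbind(e@cx + ct * px - st * py, e@cy + st * px + ct * py)
    k <- fitConic5(pts)
    expect_false(is.null(k))
    expect_lt(max(abs(conicResidual(k, pts))), 1e-6)
    ko <- svdConicOracle(pts)
    g1 <- conicToEllipse(k); g2 <- conicToEllipse(ko)
    expect_lt(abs(g1@cx - g2@cx), 1e-6)
    expect_lt(abs(g1@a - g2@a), 1e-6)
    expect_lt(abs(g1@b - g2@b), 1e-6)
  }
})

test_that("degenerate five-point configurations are flagged", {
  expect_null(fitConic5(cbind(0:4, 0:4)))                      # collinear
  expect_null(fitConic5(rbind(c(0, 0), c(0, 0), c(1, 2), c(3, 1), c(2, 5))))
  expect_error(fitConic5(cbind(1:4, 1:4)), "five")
})

test_that("circle discriminant: circles are ellipses, hyperbolic conics are not", {
  circ <- ellipseToConic(Ellipse(10, 10, 5, 5, 0))
  expect_true(conicIsEllipse(circ))
  hyp <- ConicParams(0, -1, 0, 0, -1)   # x^2 - y^2 = 1
  expect_false(conicIsEllipse(hyp))
  expect_null(conicToEllipse(hyp))
})

test_that("three-point circle fit is exact and matches the bisector oracle", {
  c1 <- fitCircle3(rbind(c(0, 1), c(1, 0), c(0, -1)))
  expect_equal(c(c1@cx, c1@cy, c1@r), c(0, 0, 1), tolerance = 1e-9)
  expect_null(fitCircle3(rbind(c(0, 0), c(1, 0), c(2, 0))))

  # perpendicular-bisector oracle on random points of a known circle
  set.seed(3)
  for (i in 1:20) {
    t3 <- runif(3, 0, 2 * pi)
    pts <- cbind(5 + 3 * cos(t3), 5 + 3 * sin(t3))
    ci <- fitCircle3(pts)
    # bisector of chord 1-2 and chord 1-3
    m12 <- (pts[1, ] + pts[2, ]) / 2; d12 <- pts[2, ] - pts[1, ]
    m13 <- (pts[1, ] + pts[3, ]) / 2; d13 <- pts[3, ] - pts[1, ]
    A <- rbind(d12, d13)
    ctr <- solve(A, c(sum(d12 * m12), sum(d13 * m13)))
    expect_lt(max(abs(c(ci@cx, ci@cy) - ctr)), 1e-7)
    expect_lt(abs(ci@r - sqrt(sum((ctr - pts[1, ])^2))), 1e-7)
    expect_lt(max(abs(sqrt((pts[, 1] - ci@cx)^2 + (pts[, 2] - ci@cy)^2) - ci@r)), 1e-9)
  }
})

test_that("constructors canonicalise and validate", {
  e <- Ellipse(0, 0, 3, 7, 0.2)   # swapped axes
  expect_equal(c(e@a, e@b), c(7, 3))
  expect_equal(e@theta, (0.2 + pi / 2) %% pi)
  expect_error(Circle(0, 0, -1))
  expect_error(BoundingBox(0, 0, 0, 5))
  expect_equal(boxVec(BoundingBox(c(1, 2, 3, 4))), c(x = 1, y = 2, w = 3, h = 4))
})
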