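test_that("fern codes follow the pixel-comparison definition", {
  const <- matrix(0.3, 15, 15)
  pairs <- cbind(c(0, 3, 7), c(0, 4, 2), c(5, 1, 9), c(5, 8, 9))
  expect_equal(fernCode(const, pairs), 0L)

  # hand evaluation on a patch with known intensities
  p <- matrix(0, 4, 4)
  p[1, 1] <- 0.9   # (x=0, y=0)
  p[3, 2] <- 0.5   # (x=1, y=2)
  hand <- rbind(c(0, 0, 1, 2),   # 0.9 > 0.5 -> bit 1 (lsb)
                c(1, 2, 3, 3),   # 0.5 > 0   -> bit 1
                c(2, 1, 0, 0))   # 0   > 0.9 -> bit 0
  expect_equal(fernCode(p, hand), 1L + 2L)

  set.seed(2)
  for (i in 1:20) {
    k <- sample(3:10, 1)
    pr <- cbind(sample(0:14, k, TRUE), sample(0:14, k, TRUE),
                sample(0:14, k, TRUE), sample(0:14, k, TRUE))
    code <- fernCode(matrix(runif(225), 15, 15), pr)
    expect_gte(code, 0L); expect_lt(code, 2^k)
  }
  expect_error(fernCode(const, cbind(20, 0, 0, 0)), "range")
})

test_that("ensemble posterior sums match hand arithmetic", {
  ens <- fernEnsemble(nFerns = 3, nPairs = 2, threshold = 1.5, adaptiveFraction = 0, seed = 1)
  ens$posterior[] <- 0
  expect_equal(ensembleClassify(c(0, 1, 2), ens)$posteriorSum, 0)
  expect_false(ensembleClassify(c(0, 1, 2), ens)$label)

  ens$posterior[] <- 1
  r <- ensembleClassify(c(0, 1, 3), ens)
  expect_equal(r$posteriorSum, 3); expect_true(r$label)

  ens$posterior[1, 1] <- 0.2; ens$posterior[2, 2] <- 0.7; ens$posterior[3, 4] <- 0.4
  expect_equal(ensembleClassify(c(0, 1, 3), ens)$posteriorSum, 0.2 + 0.7 + 0.4)
})

test_that("adaptive posterior rule fills only unseen entries of the adaptive subset", {
  ens <- fernEnsemble(nFerns = 10, nPairs = 4, adaptiveFraction = 0.2, seed = 3)
  expect_length(ens$adaptiveIdx, 2L)  # ceiling(10 / 5)
  # before any sample: unseen adaptive entries are 0.5, others 0
  expect_true(all(ens$posterior[ens$adaptiveIdx, ] == 0.5))
  nonAd <- setdiff(1:10, ens$adaptiveIdx)
  expect_true(all(ens$posterior[nonAd, ] == 0))

  # a seen entry keeps its evidence-based posterior
  f <- ens$adaptiveIdx[1]
  ens$P[f, 3] <- 3L; ens$N[f, 3] <- 1L
  ens$P[nonAd[1], 5] <- 2L
  ens <- adaptivePosteriorUpdate(ens, 30L, 40L)
  expect_equal(ens$posterior[f, 3], 0.75)            # 3 / 4, counted
  expect_equal(ens$posterior[f, 1], 0.75)            # unseen -> ratio 30/40
  expect_equal(ens$posterior[nonAd[1], 5], 1)        # counted
  expect_equal(ens$posterior[nonAd[1], 1], 0)        # unseen non-adaptive stays 0
  expect_true(all(ens$posterior >= 0 & ens$posterior <= 1))
})

test_that("variance gate rejects below half of the initial variance", {
  base <- matrix(runif(225), 15, 15)
  v0 <- mean(base^2) - mean(base)^2
  scaleTo <- function(f) (base - mean(base)) * sqrt(f) + 0.5
  expect_false(varianceFilter(matrix(0.7, 15, 15), v0))  # constant patch
  expect_false(varianceFilter(scaleTo(0.4), v0))
  expect_true(varianceFilter(scaleTo(0.6), v0))
})

test_that("nearest-neighbour confirmation behaves at its fixed points", {
  set.seed(5)
  pos <- matrix(runif(225), 15, 15)
  neg <- matrix(runif(225), 15, 15)
  model <- list(pos = list(pos), neg = list(neg))
  same <- nnConfirm(pos, model)
  expect_gt(same$relative, 0.5); expect_true(same$label)
  asNeg <- nnConfirm(neg, model)
  expect_lt(asNeg$relative, 0.5); expect_false(asNeg$label)
  sym <- nnConfirm(pos, list(pos = list(pos), neg = list(pos)))
  expect_equal(sym$relative, 0.5)
  expect_error(nnConfirm(pos, list(pos = list(), neg = list(neg))), "model")
})
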