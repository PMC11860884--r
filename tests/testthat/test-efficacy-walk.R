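test_that("walks built from transactions follow the outcome item", {
  m <- cbind(XFC = rep(1L, 6), Y = c(1L, 1L, 1L, 1L, 1L, 1L))
  tt <- TransactionTable(m)
  w <- buildWalk(tt, "Y")
  expect_equal(walkPath(w), 0:6)            # monotone walk
  m2 <- cbind(Y = rep(c(1L, 0L), 4))
  w2 <- buildWalk(TransactionTable(m2), "Y")
  expect_equal(walkPath(w2), c(0, rep(c(1, 0), 4)))
  expect_error(buildWalk(tt, "nope"), "not in table")
  expect_error(buildWalk(TransactionTable(m[0, , drop = FALSE]), "Y"),
               "empty")
})

test_that("terminal drift matches the expected step mean", {
  em <- defaultEffectMap()
  em$p_treated[em$marker == "Hs-CRP"] <- 0.8
  co <- simulateCohort(nPatients = 2000, treatedFraction = 1,
                       effectMap = em, noiseCV = 0, seed = 21)
  tt <- codeImprovements(co)
  w <- buildWalk(tt, "Hs-CRP_improved")
  expect_lt(abs(sum(increments(w)) / 2000 - 0.6), 0.05)  # E[step]=2p-1
})

test_that("degenerate walks have exactly zero fluctuation", {
  wConst <- EfficacyWalk(rep(1, 100))
  fr <- fluctuationFunction(wConst, c(2, 4, 8))
  expect_identical(fr@F2, rep(0, 3))
  wAlt <- EfficacyWalk(rep(c(1, -1), 50))
  frA <- fluctuationFunction(wAlt, c(2, 4, 8))      # even lags
  expect_identical(frA@F2, rep(0, 3))
})

test_that("the two printed forms of F2 agree", {
  x <- simulateImprovementSequence(500, "iid", seed = 8)
  y <- c(0, cumsum(x))
  fr <- fluctuationFunction(EfficacyWalk(x), c(4, 8, 16, 32))
  for (i in seq_along(fr@lags)) {
    l <- fr@lags[i]
    d <- y[(l + 1):length(y)] - y[1:(length(y) - l)]
    expect_equal(fr@F2[i], mean((d - mean(d))^2), tolerance = 1e-10)
    expect_equal(fr@F2[i], mean(d^2) - mean(d)^2, tolerance = 1e-10)
  }
})

test_that("iid fluctuations scale as F2(l) ~ l", {
  ratio <- rowMeans(sapply(1:30, function(s) {
    x <- simulateImprovementSequence(5000, "iid", seed = 600 + s)
    fluctuationFunction(EfficacyWalk(x), c(4, 8, 16, 32))@F2 /
      c(4, 8, 16, 32)
  }))
  expect_true(all(abs(ratio - 1) < 0.10))
})

test_that("exact power laws recover their exponents to machine precision", {
  lags <- c(4, 8, 16, 32, 64)
  mk <- function(F2) new("FluctuationResult", lags = as.numeric(lags),
                         F2 = F2)
  expect_equal(fitScalingExponent(mk(lags))@alphaHat, 0.5,
               tolerance = 1e-12)
  expect_equal(fitScalingExponent(mk(lags^2))@alphaHat, 1.0,
               tolerance = 1e-12)
  expect_warning(out <- fitScalingExponent(mk(c(0, lags[-1]^2))),
                 "dropped")
  expect_equal(out@alphaHat, 1.0, tolerance = 1e-12)
  expect_error(suppressWarnings(
    fitScalingExponent(mk(c(0, 0, 0, 1, 2)))), "at least 3")
})

test_that("scale equivariance: c * increments scales F2 by c^2, alpha fixed", {
  x <- simulateImprovementSequence(800, "iid", seed = 12)
  f1 <- fitScalingExponent(fluctuationFunction(EfficacyWalk(x)))
  f3 <- fitScalingExponent(fluctuationFunction(EfficacyWalk(3 * x)))
  expect_equal(f3@F2, 9 * f1@F2, tolerance = 1e-10)
  expect_equal(f3@alphaHat, f1@alphaHat, tolerance = 1e-10)
})

test_that("lag validation rejects unstable windows", {
  w <- EfficacyWalk(simulateImprovementSequence(100, "iid", seed = 1))
  expect_error(fluctuationFunction(w, c(4, 60)), "n/2")
  expect_error(fluctuationFunction(w, 0), ">= 1")
})

test_that("permutation null is centered at 1/2 and preserves the marginal", {
  x <- simulateImprovementSequence(1000, "iid", seed = 31)
  fr <- testAlphaNull(EfficacyWalk(x), nShuffles = 199,
                      lags = c(4, 8, 16, 32, 64), seed = 7)
  expect_lt(abs(mean(fr@nullAlphas) - 0.5), 0.05)
  expect_false(is.na(nullRejected(fr)))
  expect_error(testAlphaNull(EfficacyWalk(rep(1, 100))), "degenerate")
})

test_that("super-diffusive walks are detected far above the null", {
  # plain (non-detrended) fluctuation analysis saturates near alpha = 1
  # for walks whose increments are themselves a random walk; detection
  # rests on the gap to the permutation null at 1/2, not on alpha = 1.5
  hits <- sapply(1:10, function(s) {
    x <- simulateImprovementSequence(1000, "integrated", seed = 700 + s)
    fr <- testAlphaNull(EfficacyWalk(x), nShuffles = 99, seed = s)
    c(alpha = fr@alphaHat, rej = fr@nullRejected)
  })
  expect_true(all(hits["alpha", ] > 0.8))
  expect_true(all(hits["rej", ] == 1))
})
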