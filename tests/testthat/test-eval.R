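test_that("k-fold splits are balanced, seeded partitions", {
  f <- kfoldSplit(20, k = 10, seed = 1)
  expect_equal(as.vector(table(f)), rep(2L, 10))
  expect_identical(f, kfoldSplit(20, k = 10, seed = 1))
  expect_false(identical(f, kfoldSplit(20, k = 10, seed = 2)))
  f2 <- kfoldSplit(23, k = 5, seed = 3)
  expect_equal(length(f2), 23)
  expect_true(all(diff(sort(table(f2))) <= 1))
  expect_error(kfoldSplit(5, k = 10), "smaller k")
})

test_that("partial ROC matches a naive full-enumeration oracle", {
  set.seed(77)
  pres <- runif(5); bg <- runif(20)
  # fraction 1 with a deterministic identity resample via seed workaround:
  # compare the ratio of the observed (un-resampled) curve directly
  mine <- riverscape:::.pAUCratio(
    riverscape:::.rocPoints(pres, bg)$x,
    c(0, riverscape:::.fracAtLeast(pres,
                                   sort(unique(c(pres, bg)),
                                        decreasing = TRUE))),
    E = 0.1)
  expect_equal(mine, naivePAUCratio(pres, bg, 0.1), tolerance = 1e-6)

  # the bootstrap path agrees with the oracle replicate-by-replicate
  out <- partialROC(pres, bg, E = 0.1, iterations = 50, fraction = 1,
                    seed = 123)
  set.seed(123)
  oracle <- vapply(1:50, function(b) {
    res <- sample(pres, 5, replace = TRUE)
    naivePAUCratio2(res, pres, bg, 0.1)
  }, numeric(1))
  expect_equal(out$ratios, oracle, tolerance = 1e-6)
})

test_that("partial ROC separates signal from noise", {
  set.seed(5)
  bg <- runif(1000)
  # perfect separation: near-maximal ratio for E = 0.05
  hi <- partialROC(runif(50, 1.1, 2), bg, E = 0.05, iterations = 300,
                   seed = 1)
  expect_gt(hi$aucRatioMean, 1.9)
  expect_lt(hi$pValue, 0.05)

  # null: mean ratio within 2 bootstrap SEs of 1
  nl <- partialROC(sample(bg, 200), bg, E = 0.05, iterations = 300,
                   seed = 2)
  expect_lt(abs(nl$aucRatioMean - 1), 2 * sd(nl$ratios))

  # degenerate scores: ratio pinned at 1 with a warning
  expect_warning(dg <- partialROC(rep(0.5, 12), rep(0.5, 40)), "identical")
  expect_equal(dg$aucRatioMean, 1)
})

test_that("omission rate counts test presences below the threshold", {
  sc <- seq(0.05, 1, 0.05)  # 20 scores
  expect_equal(omissionRate(sc, min(sc)), 0)
  expect_equal(omissionRate(sc, 2), 1)
  expect_equal(omissionRate(sc, sort(sc)[3]), 0.10)
  expect_error(omissionRate(numeric(), 0.5), "empty")
})

test_that("AICc follows the corrected-likelihood formula", {
  # all-zero model over B background points: LL = -n log B
  spec <- fitNormalizers(featureSpec("l"), data.frame(a = c(0, 1)))
  B <- 50
  m0 <- new("MaxEntModel", beta = c(l_a = 0), featureSpec = spec,
            regMultiplier = 1, regWeights = c(l_a = 1), logZ = log(B),
            entropy = log(B),
            meta = list(nPresence = 12, nBackground = B))
  pres <- data.frame(a = runif(12))
  expect_equal(aicc(m0, pres), 2 * 12 * log(B))

  # k = n - 1 pole: excluded as +Inf
  m1 <- new("MaxEntModel", beta = c(l_a = 0.3), featureSpec = spec,
            regMultiplier = 1, regWeights = c(l_a = 1), logZ = 0.1,
            entropy = 1, meta = list(nPresence = 2, nBackground = B))
  expect_equal(aicc(m1, data.frame(a = c(0.2, 0.8))), Inf)

  # spreadsheet recomputation on a small fitted model
  set.seed(9)
  bg <- data.frame(a = runif(100))
  pr <- bg[sample(100, 25, prob = bg$a + 0.1), , drop = FALSE]
  fit <- fitMaxent(pr, bg, featureSpec("l"))
  raw <- predictSuitability(fit, pr)@raw
  k <- sum(abs(coef(fit)) > 0); n <- 25
  byHand <- -2 * sum(log(raw)) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  expect_equal(aicc(fit, pr), byHand)

  # AICc strictly increases with k at fixed LL and n
  a5 <- function(k) 2 * k + 2 * k * (k + 1) / (30 - k - 1)
  expect_true(all(diff(vapply(1:10, a5, numeric(1))) > 0))
})

test_that("best-model selection applies significance, omission, then AICc", {
  cand <- data.frame(
    regMultiplier = c(1, 1, 2, 0.5),
    classes = c("l", "lq", "lq", "lqh"),
    procAucMean = c(1.6, 1.7, 1.5, 1.1),
    procPValue = c(0.001, 0.002, 0.01, 0.4),
    omissionRate = c(0.04, 0.03, 0.20, 0.01),
    aicc = c(102.0, 98.5, 90.0, 80.0),
    nParameters = c(2, 4, 3, 9))
  best <- selectBest(cand, E = 0.05, alpha = 0.05)
  # the 90.0 candidate fails omission; the 80.0 one fails significance
  expect_equal(best$aicc, 98.5)
  expect_false(attr(best, "omissionRelaxed"))
  expect_equal(best$deltaAicc, 98.5 - 90.0)

  # omission filter empties the set: fall back to minimal omission, flagged
  tight <- selectBest(cand, E = 0.01, alpha = 0.05)
  expect_true(attr(tight, "omissionRelaxed"))
  expect_equal(tight$omissionRate, 0.03)

  expect_error(selectBest(cand[4, ], E = 0.05, alpha = 0.05),
               "no admissible model")

  # ties: fewer parameters, then lower multiplier
  tie <- data.frame(regMultiplier = c(2, 1), classes = c("l", "l"),
                    procAucMean = 1.5, procPValue = 0.01,
                    omissionRate = 0.0, aicc = 100, nParameters = c(3, 3))
  expect_equal(selectBest(tie)$regMultiplier, 1)
})

test_that("candidate evaluation ranks informative models first", {
  set.seed(31)
  B <- 600
  bg <- data.frame(t = runif(B, 0, 10), u = runif(B))
  pres <- bg[sample(B, 60, prob = plogis(-4 + bg$t)), ]
  ev <- evaluateCandidates(pres, bg, regMultipliers = 1,
                           classes = c("l", "lq"), k = 5,
                           iterations = 150, seed = 2)
  expect_equal(nrow(ev$candidates), 2)
  expect_true(all(ev$candidates$procAucMean > 1))
  expect_true(all(ev$candidates$procPValue < 0.05))
  expect_s4_class(ev$models[[paste0("m", ev$best$regMultiplier, "_",
                                    ev$best$classes)]], "MaxEntModel")
})
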