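test_that("occurrence cleaning drops vague, off-grid and duplicate records", {
  grid <- elevationGrid(matrix(100, 10, 10), 100, origin = c(0, 1000))
  occ <- data.frame(
    species = "sp",
    x = c(50, 150, 150, 5000, 250, 350, 450),
    y = c(950, 850, 860, 500, 750, 650, 550),
    uncertainty_m = c(10, 20, 30, 10, 250, 10, 10))
  out <- cleanOccurrences(occ, grid)
  rep <- attr(out, "dropReport")
  expect_equal(unname(rep["uncertain"]), 1)   # 250 m > 100 m
  expect_equal(unname(rep["offGrid"]), 1)     # x = 5000 outside
  expect_equal(unname(rep["duplicate"]), 1)   # two records in one cell
  expect_equal(nrow(out), 4)

  # clean inputs pass through with an empty drop report
  ok <- data.frame(species = "sp", x = seq(50, 950, 100), y = 950,
                   uncertainty_m = 10)
  out2 <- cleanOccurrences(ok, grid)
  expect_equal(nrow(out2), 10)
  expect_equal(sum(attr(out2, "dropReport")[c("uncertain", "offGrid",
                                              "duplicate")]), 0)

  expect_error(cleanOccurrences(data.frame(species = "sp", x = 1e9, y = 1e9,
                                           uncertainty_m = 5), grid),
               "no usable occurrences")
})

test_that("background sampling is buffered, seeded and reproducible", {
  land <- attributedLandscape(64, seed = 41, grainKm = 0.4)
  net <- land$network
  rd <- reachTable(net)
  mid <- reachGeometry(net)[[1]][1, ]
  occ <- data.frame(x = mid[1], y = mid[2])

  # buffer covering the whole grid: every reach is in the pool
  all1 <- sampleBackground(occ, net, bufferKm = 1000,
                           nBackground = nrow(rd), seed = 5)
  expect_setequal(all1, rd$id)

  # determinism
  s1 <- sampleBackground(occ, net, 2, nBackground = 20, seed = 9)
  s2 <- sampleBackground(occ, net, 2, nBackground = 20, seed = 9)
  expect_identical(s1, s2)

  # sample is a subset of the brute-force buffer intersection
  rad <- 2 * 1000
  bruteIn <- vapply(seq_len(nrow(rd)), function(i) {
    g <- reachGeometry(net)[[i]]
    any(sqrt((g[, 1] - occ$x)^2 + (g[, 2] - occ$y)^2) <= rad)
  }, logical(1))
  expect_true(all(s1 %in% rd$id[bruteIn]))
})

test_that("feature expansion follows the documented formulas", {
  bg <- data.frame(v = c(0, 5, 10), w = c(2, 4, 6))
  spec <- fitNormalizers(featureSpec("lq"), bg)

  # linear-only: min-max scaled column
  lin <- expandFeatures(data.frame(v = c(0, 2.5, 10), w = c(2, 3, 6)),
                        fitNormalizers(featureSpec("l"), bg))
  expect_equal(unname(lin[, "l_v"]), c(0, 0.25, 1))

  # quadratic at the variable max is exactly 1
  qd <- expandFeatures(data.frame(v = 10, w = 6), spec)
  expect_equal(unname(qd[1, c("q_v", "q_w")]), c(1, 1))

  # hinge ramps match the closed form at 5 knots
  hs <- fitNormalizers(featureSpec("h", nKnots = 5), bg["v"])
  vals <- data.frame(v = seq(0, 10, 2.5))
  H <- expandFeatures(vals, hs)
  kf <- seq(0, 1, length.out = 6)[-6]
  sv <- vals$v / 10
  for (j in seq_along(kf))
    expect_equal(unname(H[, sprintf("hf_v_%03d", j)]),
                 pmax(0, (sv - kf[j]) / (1 - kf[j])))
  kr <- seq(0, 1, length.out = 6)[-1]
  for (j in seq_along(kr))
    expect_equal(unname(H[, sprintf("hr_v_%03d", j)]),
                 pmax(0, (kr[j] - sv) / kr[j]))

  # transfer clamps outside the training range
  cl <- expandFeatures(data.frame(v = c(-5, 20), w = c(2, 6)), spec)
  expect_equal(unname(cl[, "l_v"]), c(0, 1))

  # degenerate predictor omitted with warning
  dg <- fitNormalizers(featureSpec("l"), data.frame(v = c(1, 2),
                                                    k = c(3, 3)))
  expect_warning(m <- expandFeatures(data.frame(v = 1.5, k = 3), dg),
                 "degenerate")
  expect_equal(colnames(m), "l_v")
})

test_that("the fitter agrees with an independent convex-optimizer oracle", {
  set.seed(42)
  n <- 60; B <- 400
  pres <- data.frame(a = rnorm(n, 1), b = runif(n))
  bg <- data.frame(a = rnorm(B), b = runif(B))
  spec <- fitNormalizers(featureSpec("lq"), bg)
  fit <- fitMaxent(pres, bg, spec, regMultiplier = 1, tol = 1e-9)

  # oracle: L-BFGS-B on the split beta+/beta- formulation of the same
  # penalized likelihood
  Fp <- expandFeatures(pres, spec); Fb <- expandFeatures(bg, spec)
  lam <- fit@regMultiplier * fit@regWeights
  sp <- colSums(Fp); np <- nrow(Fp); k <- ncol(Fb)
  lse <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  obj <- function(th) {
    beta <- th[1:k] - th[(k + 1):(2 * k)]
    np * lse(Fb %*% beta) - sum(sp * beta) + sum(lam * (th[1:k] +
                                                        th[(k + 1):(2 * k)]))
  }
  grd <- function(th) {
    beta <- th[1:k] - th[(k + 1):(2 * k)]
    eta <- drop(Fb %*% beta)
    q <- exp(eta - lse(eta))
    gs <- np * drop(crossprod(Fb, q)) - sp
    c(gs + lam, -gs + lam)
  }
  o <- optim(rep(0, 2 * k), obj, grd, method = "L-BFGS-B", lower = 0,
             control = list(maxit = 2000, factr = 1e3))
  betaO <- o$par[1:k] - o$par[(k + 1):(2 * k)]
  expect_lt(max(abs(coef(fit) - betaO)), 1e-4)
})

test_that("null data gives the uniform maximum-entropy solution", {
  set.seed(7)
  bg <- data.frame(a = rnorm(300), b = runif(300))
  fit <- fitMaxent(bg, bg, featureSpec("lq"), regMultiplier = 1)
  expect_true(all(abs(coef(fit)) <= 1e-3))
  pr <- predictSuitability(fit, bg)
  expect_lt(diff(range(pr@raw)), 1e-6)   # uniform within tolerance
})

test_that("fitted models are normalized, entropy-consistent, and sign-correct", {
  set.seed(13)
  B <- 500
  bg <- data.frame(t = runif(B, 0, 10), u = runif(B))
  # virtual species with positive linear response to t
  suit <- plogis(-3 + 0.8 * bg$t)
  idx <- sample(B, 80, prob = suit)
  pres <- bg[idx, ]
  fit <- fitMaxent(pres, bg, featureSpec("l"), regMultiplier = 1)
  expect_gt(coef(fit)[["l_t"]], 0)

  pr <- predictSuitability(fit, bg)
  expect_equal(sum(pr@raw), 1, tolerance = 1e-8)
  H <- -sum(pr@raw * log(pr@raw))
  expect_equal(H, fit@entropy, tolerance = 1e-6)

  # regularization monotonicity: non-zero features non-increasing in m
  nz <- vapply(c(0.5, 1, 2, 5, 20), function(m)
    sum(abs(coef(fitMaxent(pres, bg, featureSpec("lq"),
                           regMultiplier = m))) > 1e-12), numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("prediction transforms are monotone and rank-preserving", {
  set.seed(3)
  bg <- data.frame(a = runif(200))
  pres <- data.frame(a = runif(40, 0.5, 1))
  fit <- fitMaxent(pres, bg, featureSpec("l"))
  sm <- predictSuitability(fit, bg)
  expect_identical(order(sm@raw), order(sm@value))
  expect_true(all(sm@value >= 0 & sm@value <= 1))
  lg <- predictSuitability(fit, bg, transform = "logistic")
  expect_identical(order(lg@value), order(sm@value))
  expect_error(predictSuitability(fit, data.frame(zz = 1)),
               "missing predictors: a")
})

test_that("models survive a JSON round trip", {
  set.seed(21)
  bg <- data.frame(a = runif(150), b = rnorm(150))
  pres <- bg[sample(150, 30, prob = plogis(3 * bg$a)), ]
  fit <- fitMaxent(pres, bg, featureSpec("lq"))
  path <- tempfile(fileext = ".json")
  writeMaxEntModel(fit, path)
  back <- readMaxEntModel(path)
  expect_equal(coef(back), coef(fit))
  expect_equal(back@logZ, fit@logZ)
  p1 <- predictSuitability(fit, bg)@value
  p2 <- predictSuitability(back, bg)@value
  expect_equal(p1, p2)
})
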