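suitMap <- function(vals, species = "sp") {
  nm <- as.character(seq_along(vals))
  new("SuitabilityMap", raw = setNames(vals / sum(vals), nm),
      value = setNames(vals, nm), transform = "cloglog", species = species)
}

test_that("training-presence thresholds behave as defined", {
  expect_equal(thresholdMTP(c(0.2, 0.5, 0.9)), 0.2)
  expect_equal(thresholdMTP(0.42), 0.42)

  sc <- sort(runif(20))
  expect_equal(thresholdP10(sc), sc[2])        # ceiling(2) -> 2nd smallest
  expect_equal(omissionRate(sc, thresholdMTP(sc)), 0)

  # all-equal scores: threshold is that value, omission 0
  eq <- rep(0.3, 15)
  expect_equal(thresholdP10(eq), 0.3)
  expect_equal(omissionRate(eq, thresholdP10(eq)), 0)

  # n = 255: 26th smallest, training omission <= 0.102
  set.seed(255)
  sc255 <- runif(255)
  thr <- thresholdP10(sc255)
  expect_equal(thr, sort(sc255)[26])
  expect_lte(omissionRate(sc255, thr), 26 / 255)
  expect_lte(26 / 255, 0.102)

  expect_warning(thresholdP10(runif(5)), "fewer than 10")
  expect_error(thresholdMTP(numeric()), "empty")
})

test_that("P10 dominates MTP so its suitable set is nested", {
  for (seed in 1:5) {
    set.seed(seed)
    train <- runif(40)
    expect_gte(thresholdP10(train), thresholdMTP(train))
    sm <- suitMap(runif(120))
    bMTP <- binarize(sm, thresholdMTP(train), "MTP")
    bP10 <- binarize(sm, thresholdP10(train), "P10")
    expect_true(all(!bP10@suitable | bMTP@suitable))  # P10 subset of MTP
  }
})

test_that("binarization uses the >= tie rule", {
  sm <- suitMap(seq(0, 1, length.out = 101))
  expect_true(all(binarize(sm, 0, "MTP")@suitable))
  expect_false(any(binarize(sm, 1.1, "MTP")@suitable))
  med <- binarize(sm, median(sm@value), "P10")
  expect_equal(sum(med@suitable), 51)  # ties at the median count as suitable
})

test_that("suitable length sums the right reaches", {
  net <- toyNetwork(data.frame(id = 1:6, downstream = c(2, 3, NA, 5, 6, NA),
                               lengthKm = c(1, 2, 0.5, 1.5, 1, 3)))
  vals <- setNames(c(0.9, 0.1, 0.8, 0.2, 0.95, 0.05), as.character(1:6))
  sm <- new("SuitabilityMap", raw = vals / sum(vals), value = vals,
            transform = "cloglog", species = "sp")
  none <- binarize(sm, 2, "MTP")
  expect_equal(suitableLength(none, net), 0)
  all_ <- binarize(sm, 0, "MTP")
  expect_equal(suitableLength(all_, net), 9)
  half <- binarize(sm, 0.5, "MTP")
  expect_equal(suitableLength(half, net), 1 + 0.5 + 1)  # reaches 1, 3, 5
})

test_that("overlap percentages and lengths follow the native-denominator rule", {
  net <- toyNetwork(data.frame(id = 1:300,
                               downstream = c(2:300, NA),
                               lengthKm = rep(1, 300)))
  mkBin <- function(sel, sp) new("BinaryMap",
    suitable = setNames(seq_len(300) %in% sel, as.character(1:300)),
    threshold = 0.5, rule = "MTP", species = sp, network = "toy")

  nat <- mkBin(1:200, "native")
  # identical maps: 100%
  ov <- habitatOverlap(nat, mkBin(1:200, "twin"), net)
  expect_equal(ov$pairs$percentReaches, 100)
  # disjoint: 0%
  ov0 <- habitatOverlap(nat, mkBin(201:300, "other"), net)
  expect_equal(ov0$pairs$percentReaches, 0)
  # 116 of 200 shared -> 58%
  inv <- mkBin(c(1:116, 250:280), "invader")
  ov58 <- habitatOverlap(nat, inv, net)
  expect_equal(ov58$pairs$percentReaches, 58)
  expect_equal(ov58$pairs$sharedKm, 116)
  # shared km is symmetric
  sym <- habitatOverlap(inv, nat, net)
  expect_equal(sym$pairs$sharedKm, ov58$pairs$sharedKm)
  # shared <= min of the two suitable lengths
  expect_lte(ov58$pairs$sharedKm,
             min(ov58$pairs$nativeKm, ov58$pairs$invaderKm))

  # union percent >= every pairwise percent, on random maps
  set.seed(12)
  for (i in 1:5) {
    nt <- mkBin(sample(300, 150), "native")
    i1 <- mkBin(sample(300, 100), "a")
    i2 <- mkBin(sample(300, 100), "b")
    res <- habitatOverlap(nt, list(i1, i2), net)
    expect_gte(res$union$percentReaches + 1e-9,
               max(res$pairs$percentReaches))
  }

  # empty native: NA percent with warning
  expect_warning(na <- habitatOverlap(mkBin(integer(), "native"),
                                      mkBin(1:10, "x"), net))
  expect_true(is.na(na$pairs$percentReaches))
})

test_that("elevation comparisons use the standard rank tests", {
  land <- attributedLandscape(64, seed = 51, grainKm = 0.4)
  net <- land$network
  rd <- reachTable(net)
  ids <- rd$id

  # identical groups: no difference
  g <- list(a = ids[1:10], b = ids[1:10])
  same <- elevationCompare(g, net)
  expect_gt(same$global$pValue, 0.9)

  # hand-ranked Kruskal-Wallis oracle on three small groups
  x <- list(a = c(1, 3, 5), b = c(2, 4, 6), c = c(70, 80, 90))
  rk <- rank(unlist(x))
  n <- 9
  Rbar <- tapply(rk, rep(names(x), lengths(x)), sum)
  H <- 12 / (n * (n + 1)) * sum(Rbar^2 / 3) - 3 * (n + 1)
  kw <- kruskal.test(unlist(x), factor(rep(names(x), lengths(x))))
  expect_equal(unname(kw$statistic), H)

  expect_error(elevationCompare(list(a = ids[1], b = ids[2:4]), net),
               "singleton")
})

test_that("well-separated elevations give p < 0.01", {
  # two groups offset by 1000 m with no overlap, n = 30 each
  z <- matrix(c(seq(100, 390, 10), seq(1100, 1390, 10)), 1, 60)
  dem <- elevationGrid(z, 100, origin = c(0, 100))
  rd <- data.frame(id = 1:60, segment = 1:60, order = 1L, lengthKm = 0.1,
                   fromNode = NA, toNode = NA,
                   downstream = NA_integer_, downRow = 1L,
                   downCol = 1:60, midRow = 1L, midCol = 1:60,
                   elevationM = as.numeric(z))
  geoms <- lapply(1:60, function(i) cbind(x = c(0, 100), y = c(0, 0)))
  net <- new("StreamNetwork", reaches = rd, geometry = geoms,
             nodes = data.frame(id = integer(), x = numeric(),
                                y = numeric(), row = integer(),
                                col = integer(), type = character()),
             gridInfo = list(cellSize = 100, origin = c(0, 100),
                             dim = c(1L, 60L), crs = "toy"))
  out <- elevationCompare(list(low = 1:30, high = 31:60), net)
  expect_lt(out$global$pValue, 0.01)
  expect_equal(unname(out$means), c(mean(z[1:30]), mean(z[31:60])))
})
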