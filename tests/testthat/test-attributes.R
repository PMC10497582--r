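test_that("sinuosity is path length over chord", {
  straight <- cbind(x = seq(0, 1000, 100), y = 0)
  expect_equal(sinuosity(straight), 1.0)

  lpath <- cbind(x = c(0, 300, 300), y = c(0, 0, 400))  # 3-4-5 right angle
  expect_equal(sinuosity(lpath), 1.4)

  th <- seq(0, pi, length.out = 721)
  arc <- cbind(x = 500 * cos(th), y = 500 * sin(th))
  expect_equal(sinuosity(arc), pi / 2, tolerance = 0.01)

  expect_error(sinuosity(cbind(x = c(0, 1, 0), y = c(0, 1, 0))), "closed")
})

test_that("reach gradient is percent drop over path length, clamped at 0", {
  dem <- elevationGrid(matrix(c(1000, 950), 1, 2), 1000,
                       origin = c(0, 1000))
  geom <- cbind(x = c(500, 1500), y = c(500, 500))  # the two cell centres
  expect_equal(reachGradient(geom, dem), 5.0)

  flat <- elevationGrid(matrix(c(800, 800), 1, 2), 1000,
                        origin = c(0, 1000))
  expect_equal(reachGradient(geom, flat), 0.0)

  uphill <- elevationGrid(matrix(c(950, 1000), 1, 2), 1000,
                          origin = c(0, 1000))
  expect_warning(g <- reachGradient(geom, uphill), "uphill")
  expect_equal(g, 0.0)
})

test_that("upstream summaries equal brute-force catchment-mask means", {
  land <- attributedLandscape(64, seed = 31, grainKm = 0.4)
  net <- land$network
  flow <- land$ext$flow
  rd <- reachTable(net)
  set.seed(8)
  ras <- matrix(runif(prod(dim(gridValues(land$dem))), 0, 10),
                nrow(gridValues(land$dem)))
  picks <- rd$id[round(seq(1, nrow(rd), length.out = 4))]
  for (id in picks) {
    i <- match(id, rd$id)
    msk <- bruteCatchment(gridValues(flow), rd$downRow[i], rd$downCol[i])
    expect_equal(upstreamSummary(ras, flow, net, id), mean(ras[msk]))
  }
  # uniform raster: mean is the constant
  expect_equal(upstreamSummary(matrix(7, 64, 64), flow, net, picks[1]), 7)
})

test_that("confluence and stream densities use the upstream catchment", {
  land <- attributedLandscape(96, seed = 12, grainKm = 0.5)
  net <- land$network
  flow <- land$ext$flow
  rd <- reachTable(net)
  nodes <- networkNodes(net)

  # a headwater reach with no upstream confluences has density 0
  heads <- rd$id[!(rd$id %in% rd$downstream) & rd$order == 1]
  expect_equal(confluenceDensity(net, flow, heads[1]), 0)

  # outlet-most reach: brute-force node count over the catchment mask
  outlet <- rd$id[which.max(rd$catchmentKm2)]
  i <- match(outlet, rd$id)
  msk <- bruteCatchment(gridValues(flow), rd$downRow[i], rd$downCol[i])
  conf <- nodes[nodes$type == "confluence", ]
  nIn <- sum(msk[cbind(conf$row, conf$col)])
  area <- sum(msk) * cellSize(flow)^2 / 1e6
  expect_equal(confluenceDensity(net, flow, outlet), nIn / area)
  # stream density against direct reach-length summation
  inside <- msk[cbind(rd$downRow, rd$downCol)]
  expect_equal(streamDensity(net, flow, outlet),
               sum(rd$lengthKm[inside]) / area)
})

test_that("catchment area is monotone non-decreasing downstream", {
  land <- attributedLandscape(96, seed = 19, grainKm = 0.5)
  rd <- reachTable(land$network)
  ds <- match(rd$downstream, rd$id)
  ok <- is.na(ds) | rd$catchmentKm2[ds] >= rd$catchmentKm2 - 1e-9
  expect_true(all(ok))
  # source reaches respect the headwater threshold
  src <- !(rd$id %in% rd$downstream)
  expect_true(all(rd$catchmentKm2[src] >= 2.0 - 1e-9))
})

test_that("correlation filter keeps the greedy priority-ordered set", {
  set.seed(4)
  a <- rnorm(200)
  tbl <- data.frame(A = a, B = a + rnorm(200, sd = 0.4),
                    C = rnorm(200))
  # calibrate: make sure A-B correlation is above the cut
  stopifnot(abs(cor(tbl$A, tbl$B)) >= 0.7, abs(cor(tbl$A, tbl$C)) < 0.7)
  out <- correlationFilter(tbl, rMax = 0.7, priority = c("A", "B", "C"))
  expect_named(out, c("A", "C"))
  drp <- attr(out, "dropped")
  expect_equal(drp$variable, "B")
  expect_equal(drp$against, "A")
  expect_gte(drp$r, 0.7)

  # duplicated column: exactly one survives
  dup <- data.frame(x = a, y = a)
  expect_named(correlationFilter(dup), "x")

  # independent columns all survive; order-stable
  ind <- data.frame(p = rnorm(100), q = rnorm(100), r = rnorm(100))
  expect_named(correlationFilter(ind), c("p", "q", "r"))

  # constant column dropped with warning before correlation
  expect_warning(cf <- correlationFilter(data.frame(k = rep(1, 50),
                                                    v = rnorm(50))),
                 "constant")
  expect_named(cf, "v")
})

test_that("slope grid matches a hand-computed Horn kernel cell", {
  z <- matrix(c(10, 11, 12,
                13, 15, 17,
                18, 20, 22), 3, 3, byrow = TRUE)
  s <- slopeGrid(elevationGrid(z, 10, origin = c(0, 30)))
  dzdx <- ((12 + 2 * 17 + 22) - (10 + 2 * 13 + 18)) / (8 * 10)
  dzdy <- ((18 + 2 * 20 + 22) - (10 + 2 * 11 + 12)) / (8 * 10)
  expect_equal(s[2, 2], atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi * 100)
})
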