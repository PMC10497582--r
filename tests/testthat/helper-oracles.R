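# Independent brute-force oracles for the hydrology kernels. These walk the
# flow graph naively (O(n^2)) and never share code with the package kernels.

.dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
.dc <- c(1, 1, 0, -1, -1, -1, 0, 1)

# follow D8 directions downstream from (r, c); returns visited linear cells
followPath <- function(dir, r, c) {
  nr <- nrow(dir); nc <- ncol(dir)
  path <- integer(); steps <- 0
  repeat {
    path <- c(path, (c - 1) * nr + r)
    d <- dir[r, c]
    if (is.na(d) || d == 0) return(path)
    r2 <- r + .dr[d]; c2 <- c + .dc[d]
    if (r2 < 1 || c2 < 1 || r2 > nr || c2 > nc || is.na(dir[r2, c2]))
      return(path)
    r <- r2; c <- c2
    steps <- steps + 1
    if (steps > nr * nc) stop("cycle")
  }
}

# accumulation by path-walking: each cell contributes 1 to every cell on its
# downstream path (itself included)
bruteAccumulation <- function(dir) {
  nr <- nrow(dir); nc <- ncol(dir)
  acc <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(dir[r, c])) { acc[r, c] <- NA; next }
    for (i in followPath(dir, r, c)) acc[i] <- acc[i] + 1
  }
  acc
}

# TRUE iff every valid cell has a non-ascending 8-connected path to the
# grid boundary (fixed-point relaxation from the boundary inward)
allCellsDrain <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  drain <- matrix(FALSE, nr, nc)
  drain[1, ] <- drain[nr, ] <- TRUE
  drain[, 1] <- drain[, nc] <- TRUE
  drain[is.na(z)] <- NA
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(z[r, c]) || isTRUE(drain[r, c])) next
      for (k in 1:8) {
        r2 <- r + .dr[k]; c2 <- c + .dc[k]
        if (r2 < 1 || c2 < 1 || r2 > nr || c2 > nc) next
        if (!is.na(z[r2, c2]) && isTRUE(drain[r2, c2]) &&
            z[r2, c2] <= z[r, c]) {
          drain[r, c] <- TRUE; changed <- TRUE; break
        }
      }
    }
    if (!changed) break
  }
  all(drain[!is.na(z)])
}

# TRUE iff following directions never revisits a cell
isAcyclicD8 <- function(dir) {
  for (r in seq_len(nrow(dir))) for (c in seq_len(ncol(dir))) {
    if (is.na(dir[r, c])) next
    p <- tryCatch(followPath(dir, r, c), error = function(e) NULL)
    if (is.null(p) || anyDuplicated(p)) return(FALSE)
  }
  TRUE
}

# brute-force upstream catchment of a seed cell: every cell whose
# downstream path passes through the seed
bruteCatchment <- function(dir, sr, sc) {
  nr <- nrow(dir); nc <- ncol(dir)
  seed <- (sc - 1) * nr + sr
  msk <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(dir[r, c])) next
    if (seed %in% followPath(dir, r, c)) msk[r, c] <- TRUE
  }
  msk
}

# naive partial-AUC ratio: full enumeration of union thresholds, explicit
# loops, trapezoid integration over the restricted sensitivity region
naivePAUCratio <- function(pres, bg, E) {
  th <- sort(unique(c(pres, bg)), decreasing = TRUE)
  x <- 0; y <- 0
  for (t in th) {
    x <- c(x, sum(bg >= t) / length(bg))
    y <- c(y, sum(pres >= t) / length(pres))
  }
  s0 <- 1 - E
  i <- NA
  for (j in seq_along(y)) if (y[j] >= s0 - 1e-12) { i <- j; break }
  if (i > 1 && y[i] > s0) {
    f <- (s0 - y[i - 1]) / (y[i] - y[i - 1])
    x0 <- x[i - 1] + f * (x[i] - x[i - 1]); y0 <- s0
  } else { x0 <- x[i]; y0 <- y[i] }
  xs <- c(x0, x[i:length(x)], 1); ys <- c(y0, y[i:length(y)], 1)
  aMod <- 0
  for (j in seq_len(length(xs) - 1))
    aMod <- aMod + (xs[j + 1] - xs[j]) * (ys[j] + ys[j + 1]) / 2
  aMod / ((1 - x0^2) / 2)
}

# as above, but sensitivities come from a bootstrap resample while the
# threshold grid stays that of the original presence + background scores
naivePAUCratio2 <- function(res, pres, bg, E) {
  th <- sort(unique(c(pres, bg)), decreasing = TRUE)
  x <- 0; y <- 0
  for (t in th) {
    x <- c(x, sum(bg >= t) / length(bg))
    y <- c(y, sum(res >= t) / length(res))
  }
  s0 <- 1 - E
  i <- NA
  for (j in seq_along(y)) if (y[j] >= s0 - 1e-12) { i <- j; break }
  if (i > 1 && y[i] > s0) {
    f <- (s0 - y[i - 1]) / (y[i] - y[i - 1])
    x0 <- x[i - 1] + f * (x[i] - x[i - 1]); y0 <- s0
  } else { x0 <- x[i]; y0 <- y[i] }
  xs <- c(x0, x[i:length(x)], 1); ys <- c(y0, y[i:length(y)], 1)
  aMod <- 0
  for (j in seq_len(length(xs) - 1))
    aMod <- aMod + (xs[j + 1] - xs[j]) * (ys[j] + ys[j + 1]) / 2
  aMod / ((1 - x0^2) / 2)
}

# random valid DEM as an ElevationGrid
randomGrid <- function(n, seed, cellSize = 10) {
  set.seed(seed)
  elevationGrid(matrix(runif(n * n, 0, 50), n, n), cellSize,
                origin = c(0, n * cellSize))
}

# hand-built reach network: df needs id, downstream, lengthKm; straight
# east-west geometries, empty node table unless given
toyNetwork <- function(df, nodes = NULL, cellSize = 100) {
  n <- nrow(df)
  rd <- data.frame(id = df$id, segment = seq_len(n), order = NA_integer_,
                   lengthKm = df$lengthKm, fromNode = NA_integer_,
                   toNode = NA_integer_, downstream = df$downstream,
                   downRow = 1L, downCol = 1L, midRow = 1L, midCol = 1L)
  geoms <- lapply(seq_len(n), function(i) {
    m <- cbind(x = c(0, df$lengthKm[i] * 1000), y = c(i * 10, i * 10))
    m
  })
  if (is.null(nodes))
    nodes <- data.frame(id = integer(), x = numeric(), y = numeric(),
                        row = integer(), col = integer(),
                        type = character())
  new("StreamNetwork", reaches = rd, geometry = geoms, nodes = nodes,
      gridInfo = list(cellSize = cellSize, origin = c(0, 1000),
                      dim = c(10L, 10L), crs = "toy"))
}

# a 3-row trench DEM producing one straight stream channel flowing east
trenchDEM <- function(ncols = 101, cellSize = 100) {
  z <- matrix(0, 3, ncols)
  z[2, ] <- 100 - seq_len(ncols)
  z[1, ] <- z[2, ] + 10
  z[3, ] <- z[2, ] + 10
  elevationGrid(z, cellSize, origin = c(0, 3 * cellSize))
}

# an attributed synthetic landscape shared by the heavier model tests
attributedLandscape <- function(n = 128, seed = 11, grainKm = 0.5,
                                cellSize = 100) {
  dem <- generateDEM(n, n, cellSize, "dendritic", seed = seed)
  ext <- extractStreamNetwork(dem, grainKm = grainKm)
  rs <- generateEnvRasters(dem, c("temperature", "precipitation"),
                           seed = seed + 1)
  net <- attributeReaches(ext$network, ext$filled, ext$flow, ext$acc, rs)
  list(dem = dem, ext = ext, rasters = rs, network = net)
}
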