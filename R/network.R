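# Neighbour offsets matching the C++ kernels (clockwise from East).
.DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
.DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

#' Vectorize stream cells and split into fixed-grain reaches
#'
#' Traces channel polylines cell-centre to cell-centre along the D8 flow
#' field, breaks the network at confluences, then subdivides every
#' confluence-to-confluence (or source/outlet) segment from its upstream end
#' into reaches of length `grainKm`. A terminal remainder at least 1% of the
#' grain becomes its own reach; smaller remainders are merged into the
#' previous reach so no sliver reaches arise. Strahler orders are assigned on
#' the result.
#'
#' @param mask logical stream-cell mask from [delineateStreams()].
#' @param flow the [D8Flow-class] the mask was derived from.
#' @param dem the source [ElevationGrid-class] (geometry metadata).
#' @param grainKm target reach length in km.
#' @return a [StreamNetwork-class].
#' @export
vectorizeAndSplit <- function(mask, flow, dem, grainKm = 1.0) {
  stopifnot(is(flow, "D8Flow"), is(dem, "ElevationGrid"), grainKm > 0)
  dir <- flow@direction
  nr <- nrow(dir); nc <- ncol(dir)
  cs <- flow@cellSize; org <- flow@origin
  isStream <- !is.na(mask) & mask
  if (!any(isStream)) stop("empty stream mask: nothing to vectorize")

  sidx <- which(isStream)                      # column-major linear indices
  streamFlag <- logical(nr * nc); streamFlag[sidx] <- TRUE

  # receiver linear index per stream cell (NA when draining off-network)
  rows <- ((sidx - 1L) %% nr) + 1L
  cols <- ((sidx - 1L) %/% nr) + 1L
  d <- dir[sidx]
  recv <- rep(NA_integer_, length(sidx))
  hasd <- !is.na(d) & d > 0L
  rn <- rows[hasd] + .DR[d[hasd]]
  cn <- cols[hasd] + .DC[d[hasd]]
  inb <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
  lin <- rep(NA_integer_, sum(hasd))
  lin[inb] <- (cn[inb] - 1L) * nr + rn[inb]
  lin[!is.na(lin) & !streamFlag[ifelse(is.na(lin), 1L, lin)]] <- NA_integer_
  recv[hasd] <- lin

  pos <- integer(nr * nc); pos[sidx] <- seq_along(sidx)  # linear -> stream row
  donorCount <- integer(length(sidx))
  tt <- table(recv[!is.na(recv)])
  donorCount[pos[as.integer(names(tt))]] <- as.integer(tt)

  isJunction <- donorCount >= 2L
  isSource <- donorCount == 0L
  isTerminal <- is.na(recv)

  # trace segments from every source and junction cell
  starts <- which(isSource | isJunction)
  segs <- list()
  for (s in starts) {
    if (is.na(recv[s])) next                   # degenerate single-cell start
    path <- s
    cur <- s
    repeat {
      nx <- recv[cur]
      if (is.na(nx)) break
      nxp <- pos[nx]
      path <- c(path, nxp)
      if (isJunction[nxp]) break
      cur <- nxp
    }
    if (length(path) >= 2L) segs[[length(segs) + 1L]] <- path
  }
  if (!length(segs)) stop("stream mask yields no traceable segments")

  # node bookkeeping: one node per distinct cell; splits added later
  nodeKey <- character(); nodeRow <- integer(); nodeCol <- integer()
  nodeType <- character()
  nodeAt <- function(p, type) {
    key <- paste0("c", sidx[p])
    j <- match(key, nodeKey)
    if (is.na(j)) {
      nodeKey[[length(nodeKey) + 1L]] <<- key
      nodeRow[[length(nodeRow) + 1L]] <<- rows[p]
      nodeCol[[length(nodeCol) + 1L]] <<- cols[p]
      nodeType[[length(nodeType) + 1L]] <<- type
      j <- length(nodeKey)
    } else if (type == "confluence" && nodeType[j] != "confluence") {
      nodeType[j] <<- type                     # confluence outranks source/outlet
    }
    j
  }

  grain <- grainKm * 1000
  reachRows <- list(); geoms <- list()
  segFirstReach <- integer(length(segs)); segLastReach <- integer(length(segs))
  segEndCell <- integer(length(segs)); segStartCell <- integer(length(segs))
  rid <- 0L

  for (si in seq_along(segs)) {
    path <- segs[[si]]
    vr <- rows[path]; vc <- cols[path]
    verts <- cellCenterXY(vr, vc, cs, org)
    step <- sqrt(diff(verts[, 1])^2 + diff(verts[, 2])^2)
    cum <- c(0, cumsum(step))
    L <- cum[length(cum)]

    fromType <- if (isSource[path[1]]) "source" else "confluence"
    endP <- path[length(path)]
    toType <- if (isTerminal[endP]) "outlet" else "confluence"
    fromNode <- nodeAt(path[1], fromType)
    toNode <- nodeAt(endP, toType)

    # split boundaries from the upstream end
    nb <- floor(L / grain + 1e-12)
    if (nb >= 1 && abs(L - nb * grain) < 1e-6 * max(L, grain)) nb <- nb - 1
    bounds <- grain * seq_len(max(nb, 0L))
    if (length(bounds) && (L - bounds[length(bounds)]) < 0.01 * grain)
      bounds <- bounds[-length(bounds)]

    pieceEnds <- c(bounds, L)
    pieceStarts <- c(0, bounds)
    prevReach <- NA_integer_
    prevNode <- fromNode
    for (pi in seq_along(pieceEnds)) {
      a <- pieceStarts[pi]; b <- pieceEnds[pi]
      geom <- .slicePolyline(verts, cum, a, b)
      rid <- rid + 1L
      endNode <- if (pi == length(pieceEnds)) toNode else {
        nodeKey[[length(nodeKey) + 1L]] <- paste0("s", rid)
        pcell <- .nearestPathCell(cum, b, vr, vc)
        nodeRow[[length(nodeRow) + 1L]] <- pcell[1]
        nodeCol[[length(nodeCol) + 1L]] <- pcell[2]
        nodeType[[length(nodeType) + 1L]] <- "split"
        length(nodeKey)
      }
      dcell <- .nearestPathCell(cum, b, vr, vc)
      mcell <- .nearestPathCell(cum, (a + b) / 2, vr, vc)
      reachRows[[rid]] <- data.frame(
        id = rid, segment = si, order = NA_integer_,
        lengthKm = (b - a) / 1000,
        fromNode = prevNode, toNode = endNode, downstream = NA_integer_,
        downRow = dcell[1], downCol = dcell[2],
        midRow = mcell[1], midCol = mcell[2])
      geoms[[rid]] <- geom
      if (!is.na(prevReach)) reachRows[[prevReach]]$downstream <- rid
      prevReach <- rid
      prevNode <- endNode
    }
    segFirstReach[si] <- rid - length(pieceEnds) + 1L
    segLastReach[si] <- rid
    segStartCell[si] <- sidx[path[1]]
    segEndCell[si] <- sidx[endP]
  }

  # connect last reach of each segment to the first reach of the segment
  # starting at its end cell
  startOfCell <- integer(nr * nc)
  startOfCell[segStartCell] <- seq_along(segs)
  for (si in seq_along(segs)) {
    dsSeg <- startOfCell[segEndCell[si]]
    if (dsSeg > 0 && dsSeg != si)
      reachRows[[segLastReach[si]]]$downstream <- segFirstReach[dsSeg]
  }

  reaches <- do.call(rbind, reachRows)
  nodes <- data.frame(id = seq_along(nodeKey), row = nodeRow, col = nodeCol,
                      type = nodeType)
  ctr <- cellCenterXY(nodes$row, nodes$col, cs, org)
  nodes$x <- ctr[, 1]; nodes$y <- ctr[, 2]

  net <- new("StreamNetwork", reaches = reaches, geometry = geoms,
             nodes = nodes[, c("id", "x", "y", "row", "col", "type")],
             gridInfo = list(cellSize = cs, origin = org,
                             dim = c(nr, nc), crs = flow@crs))
  assignStrahler(net)
}

# polyline piece between path distances a and b (interpolating endpoints)
.slicePolyline <- function(verts, cum, a, b) {
  interp <- function(s) {
    j <- findInterval(s, cum, rightmost.closed = TRUE)
    j <- min(max(j, 1L), nrow(verts) - 1L)
    t <- (s - cum[j]) / max(cum[j + 1] - cum[j], .Machine$double.eps)
    verts[j, ] + t * (verts[j + 1, ] - verts[j, ])
  }
  inside <- which(cum > a + 1e-9 & cum < b - 1e-9)
  rbind(interp(a), verts[inside, , drop = FALSE], interp(b))
}

# grid cell of the original path vertex nearest to path distance s
.nearestPathCell <- function(cum, s, vr, vc) {
  j <- which.min(abs(cum - s))
  c(vr[j], vc[j])
}

#' Assign Strahler stream orders
#'
#' Source reaches get order 1. Where tributaries meet, the downstream reach
#' takes the maximum inflowing order, incremented by one when two or more
#' inflows share that maximum; reaches between confluences inherit their
#' upstream order. Computed in one topological sweep; a cyclic network is an
#' error.
#'
#' @param network a [StreamNetwork-class].
#' @return the network with the `order` column filled.
#' @export
assignStrahler <- function(network) {
  stopifnot(is(network, "StreamNetwork"))
  rd <- network@reaches
  n <- nrow(rd)
  dsIdx <- match(rd$downstream, rd$id)
  nUp <- tabulate(dsIdx[!is.na(dsIdx)], nbins = n)
  ord <- rep(NA_integer_, n)
  # collect inflow orders at each reach as they resolve
  inMax <- rep(0L, n); inMaxCount <- rep(0L, n); pending <- nUp
  queue <- which(nUp == 0L)
  ord[queue] <- 1L
  done <- 0L
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]; done <- done + 1L
    j <- dsIdx[i]
    if (!is.na(j)) {
      if (ord[i] > inMax[j]) { inMax[j] <- ord[i]; inMaxCount[j] <- 1L }
      else if (ord[i] == inMax[j]) inMaxCount[j] <- inMaxCount[j] + 1L
      pending[j] <- pending[j] - 1L
      if (pending[j] == 0L) {
        ord[j] <- if (inMaxCount[j] >= 2L) inMax[j] + 1L else inMax[j]
        queue <- c(queue, j)
      }
    }
  }
  if (done != n) stop("cycle detected in reach topology")
  rd$order <- ord
  network@reaches <- rd
  validObject(network)
  network
}

#' Extract a reach-scale stream network from a DEM
#'
#' Convenience wrapper chaining depression filling, D8 flow directions, flow
#' accumulation, stream delineation at a catchment-area threshold, and
#' vectorization into grain-length, Strahler-ordered reaches.
#'
#' @param dem an [ElevationGrid-class].
#' @param grainKm reach length in km (default 1.0).
#' @param thresholdKm2 headwater catchment-area threshold in km2 (default 2.0).
#' @return list with elements `filled`, `flow`, `acc`, `mask`, `network`.
#' @export
extractStreamNetwork <- function(dem, grainKm = 1.0, thresholdKm2 = 2.0) {
  filled <- fillDepressions(dem)
  flow <- d8FlowDirection(filled)
  acc <- flowAccumulation(flow)
  mask <- delineateStreams(acc, thresholdKm2)
  network <- vectorizeAndSplit(mask, flow, dem, grainKm)
  list(filled = filled, flow = flow, acc = acc, mask = mask,
       network = network)
}
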