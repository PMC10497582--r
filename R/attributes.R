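#' Reach gradient
#'
#' Percent slope over a reach: `100 * (upstream elevation - downstream
#' elevation) / path length`. Apparent uphill flow (an artifact of elevation
#' noise at reach scale) is clamped to 0 with a warning.
#'
#' @param geom two-column vertex matrix of the reach polyline (map units).
#' @param dem an [ElevationGrid-class].
#' @return gradient in % slope (>= 0).
#' @export
reachGradient <- function(geom, dem) {
  stopifnot(nrow(geom) >= 2)
  z <- .sampleDEM(geom[c(1, nrow(geom)), , drop = FALSE], dem)
  if (any(is.na(z))) stop("reach endpoint falls on nodata")
  len <- sum(sqrt(diff(geom[, 1])^2 + diff(geom[, 2])^2))
  g <- 100 * (z[1] - z[2]) / len
  if (g < 0) {
    warning("apparent uphill flow; gradient clamped to 0")
    g <- 0
  }
  g
}

.sampleDEM <- function(xy, dem) {
  rc <- xyToCell(xy[, 1], xy[, 2], dem@cellSize, dem@origin,
                 dim(dem@values))
  dem@values[cbind(rc[, 1], rc[, 2])]
}

#' Sinuosity index
#'
#' Channel path length divided by the straight-line distance between reach
#' endpoints; 1 for a straight channel, larger for meandering ones.
#'
#' @param geom two-column vertex matrix of the reach polyline.
#' @return unitless sinuosity >= 1 (up to floating-point rounding).
#' @export
sinuosity <- function(geom) {
  stopifnot(nrow(geom) >= 2)
  chord <- sqrt(sum((geom[nrow(geom), ] - geom[1, ])^2))
  if (chord == 0) stop("closed reach: coincident endpoints")
  sum(sqrt(diff(geom[, 1])^2 + diff(geom[, 2])^2)) / chord
}

# catchment mask upstream of a reach's downstream cell
.reachCatchment <- function(network, flow, i) {
  rd <- network@reaches
  catchmentMask(flow, rd$downRow[i], rd$downCol[i])
}

#' Density of confluences in a reach's upstream catchment
#'
#' Number of confluence nodes inside the catchment draining to the reach's
#' downstream end, divided by the catchment area in km2.
#'
#' @param network a [StreamNetwork-class].
#' @param flow the matching [D8Flow-class].
#' @param reachId reach id.
#' @return confluence density in nodes/km2.
#' @export
confluenceDensity <- function(network, flow, reachId) {
  i <- match(reachId, network@reaches$id)
  stopifnot(!is.na(i))
  msk <- .reachCatchment(network, flow, i)
  areaKm2 <- sum(msk) * flow@cellSize^2 / 1e6
  if (areaKm2 <= 0) stop("zero catchment area")
  nd <- network@nodes[network@nodes$type == "confluence", ]
  sum(msk[cbind(nd$row, nd$col)]) / areaKm2
}

#' Stream density in a reach's upstream catchment
#'
#' Total stream length (km) inside the catchment draining to the reach's
#' downstream end, divided by the catchment area (km2). A reach counts as
#' inside the catchment when its downstream cell drains through the target
#' reach (catchments are upstream-closed, so that implies the whole reach).
#'
#' @inheritParams confluenceDensity
#' @return stream density in km/km2.
#' @export
streamDensity <- function(network, flow, reachId) {
  i <- match(reachId, network@reaches$id)
  stopifnot(!is.na(i))
  msk <- .reachCatchment(network, flow, i)
  areaKm2 <- sum(msk) * flow@cellSize^2 / 1e6
  if (areaKm2 <= 0) stop("zero catchment area")
  rd <- network@reaches
  inside <- msk[cbind(rd$downRow, rd$downCol)]
  sum(rd$lengthKm[inside]) / areaKm2
}

#' Mean of a raster over a reach's upstream catchment
#'
#' @param raster numeric matrix co-registered with the flow grid.
#' @param flow a [D8Flow-class].
#' @param network a [StreamNetwork-class].
#' @param reachId reach id.
#' @return mean over catchment cells, ignoring nodata; `NA` (with a warning)
#'   when the catchment is entirely nodata in the raster.
#' @export
upstreamSummary <- function(raster, flow, network, reachId) {
  stopifnot(all(dim(raster) == dim(flow@direction)))
  i <- match(reachId, network@reaches$id)
  stopifnot(!is.na(i))
  msk <- .reachCatchment(network, flow, i)
  v <- raster[msk]
  v <- v[!is.na(v)]
  if (!length(v)) {
    warning("catchment entirely nodata in raster; summary is NA")
    return(NA_real_)
  }
  mean(v)
}

#' Terrain slope grid (Horn's method)
#'
#' 3x3 central-difference slope on the filled DEM, reported in
#' degrees x 100. Border and nodata-adjacent cells use the nearest valid
#' neighbours by edge padding.
#'
#' @param dem an [ElevationGrid-class] (ideally depression-filled).
#' @return numeric matrix, slope in degrees * 100.
#' @export
slopeGrid <- function(dem) {
  z <- dem@values
  cs <- dem@cellSize
  nr <- nrow(z); nc <- ncol(z)
  # pad by edge replication so the kernel is defined everywhere
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  # fill nodata with cell value where possible (kernel ignores exact NA mix)
  sh <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  a <- sh(0, 0); b <- sh(0, 1); cc <- sh(0, 2)
  d <- sh(1, 0); f <- sh(1, 2)
  g <- sh(2, 0); h <- sh(2, 1); i <- sh(2, 2)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cs)
  deg <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  deg[is.na(z)] <- NA
  deg * 100
}

#' Attach the standard reach attributes
#'
#' Fills the reach table with reach gradient (% slope), sinuosity, confluence
#' density (nodes/km2), stream density (km/km2), upstream catchment area
#' (km2), mean upstream slope (degrees x 100), midpoint elevation (m), and
#' the upstream-catchment mean of every supplied environmental raster.
#'
#' @param network a [StreamNetwork-class].
#' @param dem filled [ElevationGrid-class].
#' @param flow [D8Flow-class].
#' @param acc [FlowAccumulation-class].
#' @param rasters named list of co-registered numeric matrices to summarize
#'   over each reach's upstream catchment (means).
#' @return the network with attribute columns appended to its reach table.
#' @export
attributeReaches <- function(network, dem, flow, acc, rasters = list()) {
  rd <- network@reaches
  n <- nrow(rd)
  geoms <- network@geometry
  slope <- slopeGrid(dem)
  confNodes <- network@nodes[network@nodes$type == "confluence", ]

  rd$gradientPct <- NA_real_; rd$sinuosity <- NA_real_
  rd$confluenceDensity <- NA_real_; rd$streamDensity <- NA_real_
  rd$catchmentKm2 <- NA_real_; rd$upstreamSlope <- NA_real_
  rd$elevationM <- dem@values[cbind(rd$midRow, rd$midCol)]
  for (nm in names(rasters)) rd[[paste0("ups_", nm)]] <- NA_real_

  withCallingHandlers({
    for (i in seq_len(n)) {
      rd$gradientPct[i] <- reachGradient(geoms[[i]], dem)
      rd$sinuosity[i] <- sinuosity(geoms[[i]])
      msk <- catchmentMask(flow, rd$downRow[i], rd$downCol[i])
      areaKm2 <- sum(msk) * flow@cellSize^2 / 1e6
      rd$catchmentKm2[i] <- areaKm2
      rd$confluenceDensity[i] <-
        sum(msk[cbind(confNodes$row, confNodes$col)]) / areaKm2
      inside <- msk[cbind(rd$downRow, rd$downCol)]
      rd$streamDensity[i] <- sum(rd$lengthKm[inside]) / areaKm2
      sv <- slope[msk]; sv <- sv[!is.na(sv)]
      rd$upstreamSlope[i] <- if (length(sv)) mean(sv) else NA_real_
      for (nm in names(rasters)) {
        v <- rasters[[nm]][msk]; v <- v[!is.na(v)]
        rd[[paste0("ups_", nm)]][i] <- if (length(v)) mean(v) else NA_real_
      }
    }
  }, warning = function(w) invokeRestart("muffleWarning"))

  network@reaches <- rd
  validObject(network)
  network
}

#' Greedy collinearity filter for predictors
#'
#' Walks the candidate predictors in priority order and keeps a variable only
#' if its absolute Pearson correlation with every already-kept variable stays
#' below `rMax`. Constant columns are dropped (with a warning) before any
#' correlation is computed.
#'
#' @param table data.frame of candidate predictors (one row per reach or
#'   sample point).
#' @param rMax correlation cutoff in (0, 1); variables with `|r| >= rMax`
#'   against a kept variable are dropped.
#' @param priority character vector ordering the columns by preference
#'   (defaults to column order).
#' @return the filtered data.frame, with a `dropped` attribute listing each
#'   dropped variable, the kept variable that triggered the drop, and the r.
#' @export
correlationFilter <- function(table, rMax = 0.7, priority = names(table)) {
  stopifnot(nrow(table) >= 2, rMax > 0, rMax < 1,
            all(priority %in% names(table)))
  priority <- c(priority, setdiff(names(table), priority))
  dropped <- data.frame(variable = character(), against = character(),
                        r = numeric())
  isConst <- vapply(table, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                      all(is.na(v)), logical(1))
  if (any(isConst)) {
    warning("dropping constant columns: ",
            paste(names(table)[isConst], collapse = ", "))
    dropped <- rbind(dropped,
                     data.frame(variable = names(table)[isConst],
                                against = "(constant)", r = NA_real_))
    priority <- setdiff(priority, names(table)[isConst])
  }
  kept <- character()
  for (v in priority) {
    rs <- vapply(kept, function(k)
      abs(stats::cor(table[[v]], table[[k]],
                     use = "pairwise.complete.obs")), numeric(1))
    if (all(rs < rMax)) kept <- c(kept, v)
    else {
      hit <- which(rs >= rMax)[1]
      dropped <- rbind(dropped, data.frame(variable = v,
                                           against = kept[hit],
                                           r = unname(rs[hit])))
    }
  }
  out <- table[, kept, drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}
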