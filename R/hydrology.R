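#' Fill terrain depressions
#'
#' Raises every closed sink to its pour-point elevation so that each valid
#' cell has a non-ascending 8-connected path to the grid boundary (or to a
#' nodata edge). Uses a boundary-seeded priority-flood sweep without an
#' epsilon gradient; flats created by filling are resolved later, during flow
#' direction assignment.
#'
#' @param dem an [ElevationGrid-class].
#' @return an [ElevationGrid-class] with `values >= ` the input everywhere and
#'   cells outside depressions unchanged.
#' @export
fillDepressions <- function(dem) {
  stopifnot(is(dem, "ElevationGrid"))
  if (all(is.na(dem@values))) stop("empty terrain")
  filled <- fill_depressions_cpp(dem@values)
  elevationGrid(filled, dem@cellSize, dem@origin, dem@crs)
}

#' D8 steepest-descent flow directions
#'
#' Each valid cell drains to the 8-neighbour with the steepest drop per unit
#' distance (diagonal distance = cellSize * sqrt(2)). Ties take the first
#' neighbour in clockwise order starting at East. Flat cells (possible after
#' depression filling) are pointed along shortest equal-elevation paths toward
#' the flat's spill cell. Cells on the grid edge (or beside nodata) with no
#' downslope neighbour are outlets and drain off-grid.
#'
#' @param filled a depression-filled [ElevationGrid-class].
#' @return a [D8Flow-class] direction field.
#' @export
d8FlowDirection <- function(filled) {
  stopifnot(is(filled, "ElevationGrid"))
  dir <- d8_flow_direction_cpp(filled@values)
  new("D8Flow", direction = dir, cellSize = filled@cellSize,
      origin = filled@origin, crs = filled@crs)
}

#' Flow accumulation
#'
#' Number of cells draining through each cell, including the cell itself, so
#' `count(c) = 1 + sum(count(donors of c))` and the minimum is 1. Computed in
#' a single topological sweep; a cyclic direction field is an error.
#'
#' @param flow a [D8Flow-class].
#' @return a [FlowAccumulation-class].
#' @export
flowAccumulation <- function(flow) {
  stopifnot(is(flow, "D8Flow"))
  ct <- flow_accumulation_cpp(flow@direction)
  new("FlowAccumulation", count = ct, cellSize = flow@cellSize,
      origin = flow@origin, crs = flow@crs)
}

#' Drained area per cell, in km2
#' @param acc a [FlowAccumulation-class].
#' @return numeric matrix of drained areas (km2).
#' @export
drainedAreaKm2 <- function(acc) {
  stopifnot(is(acc, "FlowAccumulation"))
  acc@count * acc@cellSize^2 / 1e6
}

#' Delineate stream cells by a catchment-area threshold
#'
#' A cell is a stream cell iff the area draining through it is at least
#' `thresholdKm2` (the headwater rule: a stream starts once its catchment
#' reaches the threshold). The resulting mask is closed downstream because
#' accumulation is non-decreasing along flow paths.
#'
#' @param acc a [FlowAccumulation-class].
#' @param thresholdKm2 minimum contributing area in km2 (> 0).
#' @return logical matrix; `TRUE` marks stream cells, `NA` nodata.
#' @export
delineateStreams <- function(acc, thresholdKm2 = 2.0) {
  stopifnot(is(acc, "FlowAccumulation"), thresholdKm2 > 0)
  area <- drainedAreaKm2(acc)
  mask <- area >= thresholdKm2
  if (!any(mask, na.rm = TRUE))
    warning("threshold exceeds every cell's drained area; empty stream mask")
  mask
}

#' Upstream catchment mask
#'
#' All cells draining through any of the given seed cells (the seeds
#' themselves included), found by breadth-first search on the reversed D8
#' graph.
#'
#' @param flow a [D8Flow-class].
#' @param rows,cols 1-based cell indices of the seed cells.
#' @return logical matrix, `TRUE` on catchment cells.
#' @export
catchmentMask <- function(flow, rows, cols) {
  stopifnot(is(flow, "D8Flow"), length(rows) == length(cols))
  catchment_mask_cpp(flow@direction, as.integer(rows), as.integer(cols))
}

# map (row, col) cell indices to cell-centre map coordinates
cellCenterXY <- function(rows, cols, cellSize, origin) {
  cbind(x = origin[1] + (cols - 0.5) * cellSize,
        y = origin[2] - (rows - 0.5) * cellSize)
}

# map coordinates to (row, col), clamped to the grid
xyToCell <- function(x, y, cellSize, origin, dim) {
  col <- pmin(pmax(ceiling((x - origin[1]) / cellSize), 1L), dim[2])
  row <- pmin(pmax(ceiling((origin[2] - y) / cellSize), 1L), dim[1])
  cbind(row = as.integer(row), col = as.integer(col))
}
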