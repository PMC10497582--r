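#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib riverscape, .registration = TRUE
NULL

#' Gridded elevation terrain
#'
#' A single-band raster of terrain heights on a square-celled, projected grid.
#' Nodata cells are stored as `NA`. The grid origin is the map coordinate of
#' the upper-left corner; cell (1, 1) is the upper-left cell.
#'
#' @slot values numeric matrix of elevations (m); `NA` marks nodata.
#' @slot cellSize cell edge length in map units (m), > 0.
#' @slot origin length-2 numeric, map (x, y) of the grid's upper-left corner.
#' @slot crs free-text identifier of the projected coordinate system.
#' @exportClass ElevationGrid
setClass("ElevationGrid",
  representation(values = "matrix", cellSize = "numeric",
                 origin = "numeric", crs = "character"),
  prototype(cellSize = 1, origin = c(0, 0), crs = "local"))

setValidity("ElevationGrid", function(object) {
  msgs <- character()
  if (!is.numeric(object@values)) msgs <- c(msgs, "values must be numeric")
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(object@origin) != 2 || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be two finite coordinates")
  v <- object@values[!is.na(object@values)]
  if (length(v) && any(!is.finite(v)))
    msgs <- c(msgs, "valid cells must hold finite elevations")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ElevationGrid construct an elevation grid
#' @param values,cellSize,origin,crs see slots
#' @export
elevationGrid <- function(values, cellSize, origin = c(0, 0), crs = "local") {
  storage.mode(values) <- "double"
  new("ElevationGrid", values = values, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin), crs = crs)
}

#' D8 single-flow-direction field
#'
#' Per-cell drainage direction codes: 1..8 are the eight compass neighbours
#' clockwise from East (E, SE, S, SW, W, NW, N, NE), 0 marks an outlet
#' (drains off-grid or into nodata), `NA` marks nodata.
#'
#' @slot direction integer matrix of codes.
#' @slot cellSize,origin,crs grid geometry, as in [ElevationGrid-class].
#' @exportClass D8Flow
setClass("D8Flow",
  representation(direction = "matrix", cellSize = "numeric",
                 origin = "numeric", crs = "character"))

setValidity("D8Flow", function(object) {
  d <- object@direction[!is.na(object@direction)]
  if (length(d) && (any(d < 0) || any(d > 8)))
    return("direction codes must be in 0..8 or NA")
  TRUE
})

#' Flow accumulation counts
#'
#' Per-cell number of cells draining through it, including itself, so the
#' minimum over valid cells is 1. Drained area is `count * cellSize^2`.
#'
#' @slot count numeric matrix of upstream cell counts (self included).
#' @slot cellSize,origin,crs grid geometry, as in [ElevationGrid-class].
#' @exportClass FlowAccumulation
setClass("FlowAccumulation",
  representation(count = "matrix", cellSize = "numeric",
                 origin = "numeric", crs = "character"))

setValidity("FlowAccumulation", function(object) {
  ct <- object@count[!is.na(object@count)]
  if (length(ct) && any(ct < 1)) return("counts must be >= 1 on valid cells")
  TRUE
})

#' Reach-split, attributed stream network
#'
#' A directed, acyclic network of stream reaches traced over cell centres.
#' `reaches` holds one row per reach; `geometry` is a parallel list of
#' two-column (x, y) vertex matrices; `nodes` are the sources, confluences,
#' outlets and reach-split points.
#'
#' @slot reaches data.frame with columns `id`, `segment`, `order` (Strahler),
#'   `lengthKm`, `fromNode`, `toNode`, `downstream` (reach id or `NA`),
#'   `downRow`, `downCol` (grid cell of the downstream end), plus any
#'   attribute columns appended later.
#' @slot geometry list of numeric matrices (vertex x, y), parallel to reaches.
#' @slot nodes data.frame with `id`, `x`, `y`, `row`, `col`,
#'   `type` in source/confluence/outlet/split.
#' @slot gridInfo list: `cellSize`, `origin`, `dim`, `crs` of the source grid.
#' @exportClass StreamNetwork
setClass("StreamNetwork",
  representation(reaches = "data.frame", geometry = "list",
                 nodes = "data.frame", gridInfo = "list"))

setValidity("StreamNetwork", function(object) {
  rd <- object@reaches
  need <- c("id", "segment", "order", "lengthKm", "downstream")
  if (!all(need %in% names(rd)))
    return(paste("reaches must have columns:", paste(need, collapse = ", ")))
  if (nrow(rd) != length(object@geometry))
    return("geometry list must parallel the reach table")
  if (nrow(rd) && any(rd$lengthKm <= 0)) return("reach lengths must be > 0")
  # downstream pointers must be acyclic
  if (nrow(rd)) {
    nxt <- match(rd$downstream, rd$id)
    depth <- rep(0L, nrow(rd))
    for (i in seq_len(nrow(rd))) {
      j <- i; steps <- 0L
      while (!is.na(j)) {
        steps <- steps + 1L
        if (steps > nrow(rd)) return("cycle in downstream reach pointers")
        j <- nxt[j]
      }
      depth[i] <- steps
    }
  }
  TRUE
})

#' Fitted maximum-entropy habitat model
#'
#' Coefficients of an L1-penalized Gibbs distribution over background reaches,
#' together with the feature expansion and normalizers needed to score new
#' reaches, the log partition sum over the training background, and the
#' entropy of the fitted background distribution (used by the cloglog output).
#'
#' @slot beta named numeric coefficients, one per expanded feature.
#' @slot featureSpec the [FeatureExpansion-class] used in fitting (with
#'   normalizers learned from the background).
#' @slot regMultiplier the regularization multiplier m.
#' @slot regWeights per-feature L1 penalty weights (before multiplying by m).
#' @slot logZ log of the background partition sum at the fitted beta.
#' @slot entropy entropy H of the fitted distribution over the background.
#' @slot meta list: presence/background sizes, seed, convergence diagnostics.
#' @exportClass MaxEntModel
setClass("MaxEntModel",
  representation(beta = "numeric", featureSpec = "ANY",
                 regMultiplier = "numeric", regWeights = "numeric",
                 logZ = "numeric", entropy = "numeric", meta = "list"))

setValidity("MaxEntModel", function(object) {
  if (any(!is.finite(object@beta))) return("coefficients must be finite")
  nb <- object@meta$nBackground
  if (!is.null(nb) && length(object@entropy) == 1 &&
      (object@entropy < -1e-8 || object@entropy > log(nb) + 1e-8))
    return("entropy must lie in [0, log(background n)]")
  TRUE
})

#' Feature expansion specification
#'
#' Which MaxEnt feature classes to build from raw predictors, plus the
#' min-max normalizers (learned from the background) that map every feature
#' into [0, 1], and the hinge/threshold knot count.
#'
#' @slot classes character vector, subset of
#'   linear/quadratic/product/hinge/threshold.
#' @slot nKnots number of hinge/threshold knots per variable.
#' @slot lower,upper named per-variable normalization bounds (background
#'   min and max); empty until fitted with [fitNormalizers()].
#' @exportClass FeatureExpansion
setClass("FeatureExpansion",
  representation(classes = "character", nKnots = "numeric",
                 lower = "numeric", upper = "numeric"))

setValidity("FeatureExpansion", function(object) {
  ok <- c("linear", "quadratic", "product", "hinge", "threshold")
  if (!all(object@classes %in% ok))
    return(paste("unknown feature class; allowed:", paste(ok, collapse = ", ")))
  if (length(object@nKnots) != 1 || object@nKnots < 1)
    return("nKnots must be a single value >= 1")
  TRUE
})

#' Continuous suitability over a set of reaches
#'
#' Raw Gibbs densities (summing to 1 over the training background) and their
#' monotone transform to the 0-1 suitability scale.
#'
#' @slot raw named numeric raw densities.
#' @slot value named numeric suitability in [0, 1] (same order as raw).
#' @slot transform "cloglog" or "logistic".
#' @slot species free-text species identifier.
#' @exportClass SuitabilityMap
setClass("SuitabilityMap",
  representation(raw = "numeric", value = "numeric", transform = "character",
                 species = "character"))

setValidity("SuitabilityMap", function(object) {
  if (length(object@raw) != length(object@value))
    return("raw and value must be parallel")
  if (length(object@value) && (any(object@value < 0) ||
                               any(object@value > 1)))
    return("suitability values must lie in [0, 1]")
  TRUE
})

setMethod("show", "SuitabilityMap", function(object) {
  cat(sprintf("SuitabilityMap (%s, %s): %d reaches, range %.3f - %.3f\n",
              object@species, object@transform, length(object@value),
              if (length(object@value)) min(object@value) else NA,
              if (length(object@value)) max(object@value) else NA))
})

#' Binary suitability map over a network
#'
#' @slot suitable logical, one entry per reach (named by reach id).
#' @slot threshold the binarization threshold on the cloglog scale.
#' @slot rule threshold rule tag, "MTP" or "P10".
#' @slot species,network free-text identifiers.
#' @exportClass BinaryMap
setClass("BinaryMap",
  representation(suitable = "logical", threshold = "numeric",
                 rule = "character", species = "character",
                 network = "character"))

setValidity("BinaryMap", function(object) {
  if (!object@rule %in% c("MTP", "P10"))
    return("rule must be 'MTP' or 'P10'")
  TRUE
})
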