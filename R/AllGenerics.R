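#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("reachTable", function(x) standardGeneric("reachTable"))
#' @rdname accessors
#' @export
setGeneric("reachTable<-", function(x, value) standardGeneric("reachTable<-"))
#' @rdname accessors
#' @export
setGeneric("reachGeometry", function(x) standardGeneric("reachGeometry"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("totalLengthKm", function(x) standardGeneric("totalLengthKm"))
#' @rdname accessors
#' @export
setGeneric("nReaches", function(x) standardGeneric("nReaches"))

#' Accessors for riverscape classes
#'
#' Small read (and for the reach table, replace) accessors so user code never
#' touches slots directly.
#'
#' @param x the object.
#' @param value replacement reach table (same number of rows).
#' @name accessors
NULL

#' @rdname accessors
setMethod("gridValues", "ElevationGrid", function(x) x@values)
#' @rdname accessors
setMethod("gridValues", "D8Flow", function(x) x@direction)
#' @rdname accessors
setMethod("gridValues", "FlowAccumulation", function(x) x@count)
#' @rdname accessors
setMethod("cellSize", "ElevationGrid", function(x) x@cellSize)
#' @rdname accessors
setMethod("cellSize", "D8Flow", function(x) x@cellSize)
#' @rdname accessors
setMethod("cellSize", "FlowAccumulation", function(x) x@cellSize)
#' @rdname accessors
setMethod("cellSize", "StreamNetwork", function(x) x@gridInfo$cellSize)
#' @rdname accessors
setMethod("gridOrigin", "ElevationGrid", function(x) x@origin)
#' @rdname accessors
setMethod("gridOrigin", "D8Flow", function(x) x@origin)
#' @rdname accessors
setMethod("gridOrigin", "FlowAccumulation", function(x) x@origin)

#' @rdname accessors
setMethod("reachTable", "StreamNetwork", function(x) x@reaches)
#' @rdname accessors
setMethod("reachTable<-", "StreamNetwork", function(x, value) {
  stopifnot(nrow(value) == nrow(x@reaches))
  x@reaches <- value
  validObject(x)
  x
})
#' @rdname accessors
setMethod("reachGeometry", "StreamNetwork", function(x) x@geometry)
#' @rdname accessors
setMethod("networkNodes", "StreamNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("totalLengthKm", "StreamNetwork",
          function(x) sum(x@reaches$lengthKm))
#' @rdname accessors
setMethod("nReaches", "StreamNetwork", function(x) nrow(x@reaches))
#' @rdname accessors
#' @param object a [MaxEntModel-class]
#' @param ... unused
#' @importFrom stats coef
#' @exportMethod coef
setMethod("coef", "MaxEntModel", function(object, ...) object@beta)

setMethod("show", "ElevationGrid", function(object) {
  v <- object@values
  cat(sprintf("ElevationGrid: %d x %d cells @ %g m (%s)\n",
              nrow(v), ncol(v), object@cellSize, object@crs))
  cat(sprintf("  elevation range: %.1f - %.1f m; nodata cells: %d\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE), sum(is.na(v))))
})

setMethod("show", "D8Flow", function(object) {
  d <- object@direction
  cat(sprintf("D8Flow: %d x %d cells; outlets: %d\n",
              nrow(d), ncol(d), sum(d == 0, na.rm = TRUE)))
})

setMethod("show", "FlowAccumulation", function(object) {
  ct <- object@count
  cat(sprintf("FlowAccumulation: %d x %d cells; max drained area %.2f km2\n",
              nrow(ct), ncol(ct),
              max(ct, na.rm = TRUE) * object@cellSize^2 / 1e6))
})

setMethod("show", "StreamNetwork", function(object) {
  rd <- object@reaches
  cat(sprintf("StreamNetwork: %d reaches, %.2f km total, max order %d\n",
              nrow(rd), sum(rd$lengthKm),
              if (nrow(rd)) max(rd$order) else 0L))
  tab <- table(object@nodes$type)
  cat("  nodes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  extra <- setdiff(names(rd), c("id", "segment", "order", "lengthKm",
                                "fromNode", "toNode", "downstream",
                                "downRow", "downCol", "midRow", "midCol"))
  if (length(extra))
    cat("  reach attributes:", paste(extra, collapse = ", "), "\n")
})

setMethod("show", "MaxEntModel", function(object) {
  nz <- sum(abs(object@beta) > 0)
  cat(sprintf(
    "MaxEntModel: %d features (%d non-zero), m = %g, H = %.3f\n",
    length(object@beta), nz, object@regMultiplier, object@entropy))
  cat(sprintf("  trained on %d presences vs %d background reaches\n",
              object@meta$nPresence, object@meta$nBackground))
})

setMethod("show", "BinaryMap", function(object) {
  cat(sprintf("BinaryMap [%s @ %.4g]: %d / %d reaches suitable (%s on %s)\n",
              object@rule, object@threshold, sum(object@suitable),
              length(object@suitable), object@species, object@network))
})
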