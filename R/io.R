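#' Read an Esri ASCII grid raster
#'
#' Plain-text single-band raster exchange format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by rows
#' from the top). Nodata cells become `NA`.
#'
#' @param path file path.
#' @param crs text CRS identifier to record (the format itself carries none).
#' @return an [ElevationGrid-class].
#' @export
readAsciiGrid <- function(path, crs = "unspecified") {
  if (!file.exists(path)) stop("cannot open ASCII grid: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, 1)), "\\s+")[[1]]
    hdr[[tolower(ln[1])]] <- as.numeric(ln[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ASCII grid: missing header fields")
  vals <- scan(con, what = numeric(), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body does not match header dimensions")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  elevationGrid(m, hdr$cellsize,
                origin = c(hdr$xllcorner,
                           hdr$yllcorner + hdr$nrows * hdr$cellsize),
                crs = crs)
}

#' Write an Esri ASCII grid raster
#'
#' @param grid an [ElevationGrid-class] (or a bare matrix plus geometry
#'   arguments matching another grid).
#' @param path output file.
#' @param nodata value used for `NA` cells (default -9999).
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  m <- grid@values
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", grid@origin[1]),
           sprintf("yllcorner %.10g", grid@origin[2] -
                     nrow(m) * grid@cellSize),
           sprintf("cellsize %.10g", grid@cellSize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export a stream network as GeoJSON
#'
#' One LineString feature per reach, its table row as properties. Node and
#' grid metadata ride along in a foreign `riverscape` member so the file
#' round-trips through [readNetworkGeoJSON()].
#'
#' @param network a [StreamNetwork-class].
#' @param path output file.
#' @export
writeNetworkGeoJSON <- function(network, path) {
  rd <- network@reaches
  feats <- lapply(seq_len(nrow(rd)), function(i) {
    props <- as.list(rd[i, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = unname(
                           lapply(seq_len(nrow(network@geometry[[i]])),
                                  function(j) unname(
                                    network@geometry[[i]][j, ])))),
         properties = props)
  })
  obj <- list(type = "FeatureCollection", features = feats,
              riverscape = list(nodes = network@nodes,
                                gridInfo = network@gridInfo))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a stream network written by [writeNetworkGeoJSON()]
#'
#' @param path GeoJSON file.
#' @return a [StreamNetwork-class].
#' @export
readNetworkGeoJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  feats <- obj$features
  rd <- feats$properties
  geoms <- lapply(feats$geometry$coordinates, function(m) {
    m <- matrix(unlist(m), ncol = 2, byrow = !is.matrix(m))
    colnames(m) <- c("x", "y")
    m
  })
  gi <- obj$riverscape$gridInfo
  new("StreamNetwork", reaches = rd, geometry = geoms,
      nodes = as.data.frame(obj$riverscape$nodes),
      gridInfo = list(cellSize = gi$cellSize, origin = unlist(gi$origin),
                      dim = unlist(gi$dim), crs = gi$crs))
}

#' Read an occurrence table
#'
#' CSV with at least `species`, `x`, `y`, `uncertainty_m` columns.
#'
#' @param path CSV file.
#' @return data.frame of occurrence records.
#' @export
readOccurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y", "uncertainty_m")
  if (!all(need %in% names(occ)))
    stop("occurrence file must have columns: ",
         paste(need, collapse = ", "))
  occ
}

#' Mirror reach attributes to CSV
#'
#' @param network a [StreamNetwork-class].
#' @param path output CSV.
#' @export
writeReachAttributes <- function(network, path) {
  utils::write.csv(network@reaches, path, row.names = FALSE)
  invisible(path)
}
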