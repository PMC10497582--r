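# Periodic Gaussian-smoothed white-noise field, sd ~ 1. FFT convolution keeps
# large grids cheap; the wrap-around is harmless for synthetic terrain.
.smoothField <- function(nr, nc, range) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- outer(exp(-dr^2 / (2 * range^2)), exp(-dc^2 / (2 * range^2)))
  k <- k / sum(k)
  f <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) /
    (nr * nc)
  f / stats::sd(f)
}

#' Generate a synthetic elevation grid
#'
#' Seeded terrain generators for testing the hydrological workflow:
#' `tilted_plane` (a depression-free eastward slope), `valley_v` (a V-shaped
#' valley whose single main stem runs east along the valley axis), and
#' `dendritic` (a tilted surface plus multi-scale smooth noise, producing
#' branching valley networks once filled and routed).
#'
#' @param rows,cols grid dimensions.
#' @param cellSize cell edge (m); default 100.
#' @param kind one of `"tilted_plane"`, `"valley_v"`, `"dendritic"`.
#' @param noiseAmp amplitude (m) of the rough small-scale noise added on top
#'   (0 keeps `tilted_plane` exactly depression-free).
#' @param relief vertical range (m) of the large-scale structure.
#' @param seed integer RNG seed; identical seeds give bit-identical grids.
#' @return an [ElevationGrid-class].
#' @export
generateDEM <- function(rows = 256, cols = 256, cellSize = 100,
                        kind = c("dendritic", "tilted_plane", "valley_v"),
                        noiseAmp = NULL, relief = 500, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(noiseAmp)) noiseAmp <- if (kind == "tilted_plane") 0 else 2
  if (rows < 2 || cols < 2) stop("grid dimensions must be at least 2 x 2")
  set.seed(seed)
  ci <- matrix(rep(seq_len(cols), each = rows), rows, cols)
  ri <- matrix(rep(seq_len(rows), cols), rows, cols)
  base <- 1000 + relief * (cols - ci) / cols        # drains toward east edge
  z <- switch(kind,
    tilted_plane = base,
    valley_v = base + relief * abs(ri - (rows + 1) / 2) / rows * 4,
    dendritic = base +
      0.6 * relief * .smoothField(rows, cols, max(4, min(rows, cols) / 10)) +
      0.15 * relief * .smoothField(rows, cols, max(2, min(rows, cols) / 40)))
  if (noiseAmp > 0) z <- z + noiseAmp * matrix(stats::rnorm(rows * cols),
                                               rows, cols)
  elevationGrid(z, cellSize, origin = c(0, rows * cellSize), crs = "synthetic")
}

#' Generate smooth environmental rasters co-registered with a grid
#'
#' One smooth Gaussian field per requested name, scaled to a plausible range
#' inferred from the name: temperature-like rasters follow an elevational
#' lapse (strong negative correlation with the terrain), precipitation-like
#' rasters are in mm, landcover-like rasters are percentages clipped to
#' [0, 100], soil-carbon-like rasters are small positive percentages; other
#' names give standardized smooth fields.
#'
#' @param dem an [ElevationGrid-class] setting dimensions (and the lapse).
#' @param names character vector of raster names.
#' @param seed integer RNG seed.
#' @param kinds optional named character vector overriding the name-based
#'   inference per raster: `"constant"` (uniform value 1), `"lapse"`,
#'   or `"smooth"`.
#' @return named list of numeric matrices, `NA` where the DEM is nodata.
#' @export
generateEnvRasters <- function(dem, names, seed = 1, kinds = character()) {
  set.seed(seed)
  z <- dem@values
  nr <- nrow(z); nc <- ncol(z)
  rng <- max(4, min(nr, nc) / 12)
  out <- lapply(names, function(nm) {
    f <- .smoothField(nr, nc, rng)
    low <- tolower(nm)
    kind <- if (nm %in% names(kinds)) kinds[[nm]] else "auto"
    r <- if (kind == "constant") {
      matrix(1, nr, nc)
    } else if (kind == "smooth") {
      f
    } else if (grepl("temp", low) || kind == "lapse") {
      # lapse-dominated: -6.5 degC/km plus mild smooth anomaly
      15 - 0.0065 * (z - min(z, na.rm = TRUE)) + 0.3 * f
    } else if (grepl("precip|rain", low)) {
      pmax(900 + 350 * f, 0)
    } else if (grepl("cover|tree|shrub|herb|land", low)) {
      pmin(pmax(50 + 25 * f, 0), 100)
    } else if (grepl("soil|carbon", low)) {
      pmax(2 + 1.2 * f, 0)
    } else f
    r[is.na(z)] <- NA
    r
  })
  stats::setNames(out, names)
}

#' Simulate a virtual species on an attributed network
#'
#' Defines a known suitability surface over reaches from a logistic
#' linear-quadratic response to (standardized) reach attributes, then samples
#' presence reaches without replacement with probability proportional to
#' suitability. Occurrence coordinates are jittered inside the reach midpoint
#' cell and carry positional uncertainties below 100 m, so occurrence
#' cleaning retains them.
#'
#' @param network an attributed [StreamNetwork-class].
#' @param linear named coefficients on standardized reach attributes.
#' @param quadratic named coefficients on squared standardized attributes.
#' @param prevalence target mean true suitability in (0, 1); the intercept is
#'   solved to hit it.
#' @param nPresence number of presence records to draw.
#' @param species species label for the records.
#' @param seed integer RNG seed.
#' @return list with `occurrences` (data.frame species, x, y, uncertainty_m,
#'   source) and `suitability` (named per-reach true suitability in [0, 1]).
#' @export
simulateVirtualSpecies <- function(network, linear, quadratic = numeric(),
                                   prevalence = 0.3, nPresence = 100,
                                   species = "virtual", seed = 1) {
  rd <- network@reaches
  if (nPresence > nrow(rd)) stop("more presences requested than reaches")
  vars <- union(names(linear), names(quadratic))
  if (!all(vars %in% names(rd)))
    stop("unknown reach attributes: ",
         paste(setdiff(vars, names(rd)), collapse = ", "))
  X <- scale(as.matrix(rd[, vars, drop = FALSE]))
  X[!is.finite(X)] <- 0
  lp <- rep(0, nrow(rd))
  for (v in names(linear)) lp <- lp + linear[[v]] * X[, v]
  for (v in names(quadratic)) lp <- lp + quadratic[[v]] * X[, v]^2
  # intercept hitting the prevalence target
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp)) - prevalence,
                       c(-50, 50))$root
  suit <- stats::plogis(b0 + lp)
  names(suit) <- rd$id

  set.seed(seed)
  picked <- sample(seq_len(nrow(rd)), nPresence, replace = FALSE,
                   prob = suit)
  cs <- network@gridInfo$cellSize
  org <- network@gridInfo$origin
  ctr <- cellCenterXY(rd$midRow[picked], rd$midCol[picked], cs, org)
  jit <- matrix(stats::runif(2 * nPresence, -0.45, 0.45) * cs, ncol = 2)
  occ <- data.frame(species = species,
                    x = ctr[, 1] + jit[, 1], y = ctr[, 2] + jit[, 2],
                    uncertainty_m = stats::runif(nPresence, 5, 95),
                    source = "virtual")
  list(occurrences = occ, suitability = suit)
}
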