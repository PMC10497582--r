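#' Write a complete synthetic study landscape to disk
#'
#' Generates a seeded terrain, environmental rasters and two virtual-species
#' occurrence sets (a cold-water "native" and a milder-preference "invader"),
#' and writes them as plain-text artifacts: `dem.asc`, one `env_<name>.asc`
#' per raster, `occurrences.csv`, and `true_suitability.csv` (the known
#' per-reach suitability of each species, for recovery checks).
#'
#' @param dir output directory (created).
#' @param kind terrain kind for [generateDEM()].
#' @param rows,cols,cellSize grid shape (default 256 x 256 at 100 m).
#' @param grainKm,thresholdKm2 network parameters used when placing species.
#' @param nPresence occurrences per species (default 80; keep this well
#'   below the reach count so presences do not saturate the network).
#' @param seed integer RNG seed.
#' @return invisibly, a named list of the written paths.
#' @export
makeFixtures <- function(dir, kind = "dendritic", rows = 256, cols = 256,
                         cellSize = 100, grainKm = 0.5, thresholdKm2 = 2.0,
                         nPresence = 80, seed = 7) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dem <- generateDEM(rows, cols, cellSize, kind, seed = seed)
  writeAsciiGrid(dem, file.path(dir, "dem.asc"))
  rasters <- generateEnvRasters(dem, c("temperature", "precipitation"),
                                seed = seed + 1)
  for (nm in names(rasters))
    writeAsciiGrid(elevationGrid(rasters[[nm]], cellSize,
                                 origin = dem@origin, crs = dem@crs),
                   file.path(dir, paste0("env_", nm, ".asc")))

  ext <- extractStreamNetwork(dem, grainKm, thresholdKm2)
  net <- attributeReaches(ext$network, ext$filled, ext$flow, ext$acc,
                          rasters)
  # both virtual species carry clearly defined niches (strong responses,
  # modest prevalence); a species indistinguishable from background would
  # make the downstream modelling study degenerate
  native <- simulateVirtualSpecies(
    net, linear = c(ups_temperature = -2, gradientPct = 0.8),
    quadratic = c(ups_temperature = -1),
    prevalence = 0.2, nPresence = nPresence, species = "native",
    seed = seed + 2)
  invader <- simulateVirtualSpecies(
    net, linear = c(ups_temperature = -1.5, ups_precipitation = 1),
    quadratic = c(ups_precipitation = -0.5),
    prevalence = 0.25, nPresence = nPresence, species = "invader",
    seed = seed + 3)
  occ <- rbind(native$occurrences, invader$occurrences)
  utils::write.csv(occ, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  truth <- data.frame(reachId = as.integer(names(native$suitability)),
                      native = unname(native$suitability),
                      invader = unname(invader$suitability))
  utils::write.csv(truth, file.path(dir, "true_suitability.csv"),
                   row.names = FALSE)
  invisible(list(dem = file.path(dir, "dem.asc"),
                 rasters = stats::setNames(
                   file.path(dir, paste0("env_", names(rasters), ".asc")),
                   names(rasters)),
                 occurrences = file.path(dir, "occurrences.csv"),
                 truth = file.path(dir, "true_suitability.csv")))
}

#' Default pipeline configuration
#'
#' Defaults mirror the study conventions: 1.0 km reach grain, 2.0 km2
#' headwater threshold, 10-fold cross-validation, E = 0.05, and a compact
#' candidate grid over regularization multipliers and feature classes.
#' `bufferKm` has a default only for convenience on synthetic landscapes;
#' real studies should set it deliberately.
#'
#' @return named list of defaults, to be merged with user config.
#' @export
defaultPipelineConfig <- function() {
  list(grainKm = 1.0, thresholdKm2 = 2.0, bufferKm = 20,
       nBackground = 10000, regMultipliers = c(0.5, 1, 2),
       classes = c("l", "lq", "lqh"), E = 0.05, alpha = 0.05,
       folds = 10, iterations = 500, fraction = 0.5, nKnots = 50,
       seed = 1)
}

#' Read a pipeline configuration file
#'
#' YAML key/value file; unspecified keys take [defaultPipelineConfig()]
#' values. Required keys: `dem`, `occurrences`, `outDir`, and a `species`
#' list with `name`, `role` (native/invader) and `thresholdRule` (MTP/P10)
#' per entry. Optional: `rasters` (named map of ASCII grid paths),
#' `receivingDem`.
#'
#' @param path YAML file.
#' @return a config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(defaultPipelineConfig(), cfg)
  out
}

.nearestReach <- function(x, y, network) {
  geoms <- network@geometry
  vapply(seq_along(x), function(i) {
    d <- vapply(geoms, function(g)
      min((g[, 1] - x[i])^2 + (g[, 2] - y[i])^2), numeric(1))
    network@reaches$id[which.min(d)]
  }, numeric(1))
}

# classify predictor columns for the correlation-filter priority order
.predictorPriority <- function(cols) {
  cls <- ifelse(grepl("temp|precip|rain", cols, ignore.case = TRUE), 1,
         ifelse(grepl("cover|tree|shrub|herb|land", cols,
                      ignore.case = TRUE), 3,
         ifelse(grepl("soil|carbon", cols, ignore.case = TRUE), 4, 2)))
  cols[order(cls, seq_along(cols))]
}

#' Run the full riverscape pipeline
#'
#' Chains extract, attribute, occurrence cleaning, background sampling,
#' candidate-model evaluation and selection, transfer to the receiving
#' network, binarization and habitat overlap, writing every intermediate
#' artifact plus a JSON manifest (parameters, seeds, per-stage status,
#' timings and artifact checksums) under `config$outDir`. When a manifest
#' from an identical configuration is already present, completed stages are
#' reused from their artifacts unless `force = TRUE`. A failing stage is
#' recorded in the manifest and downstream stages are skipped.
#'
#' @param config list (see [readPipelineConfig()]) or path to a YAML file.
#' @param force rerun stages even when cached artifacts exist.
#' @return the manifest, invisibly (also written to `outDir/manifest.json`).
#' @export
runPipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- utils::modifyList(defaultPipelineConfig(), config)
  stopifnot(!is.null(config$dem), !is.null(config$occurrences),
            !is.null(config$outDir), !is.null(config$species))
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfgHash <- digestConfig(config)
  oldManifest <- NULL
  mpath <- file.path(out, "manifest.json")
  if (!force && file.exists(mpath)) {
    om <- try(jsonlite::read_json(mpath, simplifyVector = TRUE),
              silent = TRUE)
    if (!inherits(om, "try-error") &&
        identical(om$configHash, cfgHash)) oldManifest <- om
  }
  manifest <- list(configHash = cfgHash, parameters = config,
                   stages = list(), artifacts = list())
  failed <- FALSE
  counts <- list()

  stage <- function(name, artifacts, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped (upstream failure)")
      return(NULL)
    }
    paths <- file.path(out, artifacts)
    cached <- !is.null(oldManifest) &&
      identical(oldManifest$stages[[name]]$status, "ok") &&
      all(file.exists(paths))
    t0 <- proc.time()[["elapsed"]]
    res <- if (cached) {
      manifest$stages[[name]] <<- list(status = "skipped (cached)")
      tryCatch(fun(cached = TRUE), error = function(e) e)
    } else {
      tryCatch(fun(cached = FALSE), error = function(e) e)
    }
    if (inherits(res, "error")) {
      failed <<- TRUE
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      return(NULL)
    }
    if (!cached)
      manifest$stages[[name]] <<- list(
        status = "ok",
        seconds = round(proc.time()[["elapsed"]] - t0, 3))
    for (p in paths)
      if (file.exists(p))
        manifest$artifacts[[basename(p)]] <<- unname(tools::md5sum(p))
    res
  }

  extractOne <- function(demPath, tag, cached) {
    dem <- readAsciiGrid(demPath)
    if (cached) {
      net <- readNetworkGeoJSON(file.path(out,
                                          paste0("network_", tag,
                                                 ".geojson")))
      filled <- readAsciiGrid(file.path(out, paste0("filled_", tag, ".asc")))
      flow <- d8FlowDirection(filled)
      acc <- flowAccumulation(flow)
      return(list(dem = dem, filled = filled, flow = flow, acc = acc,
                  network = net))
    }
    ext <- extractStreamNetwork(dem, config$grainKm, config$thresholdKm2)
    writeAsciiGrid(ext$filled, file.path(out, paste0("filled_", tag,
                                                     ".asc")))
    writeNetworkGeoJSON(ext$network,
                        file.path(out, paste0("network_", tag, ".geojson")))
    c(ext, list(dem = dem))
  }

  attributeOne <- function(ext, tag, cached) {
    rasters <- list()
    for (nm in names(config$rasters))
      rasters[[nm]] <- readAsciiGrid(config$rasters[[nm]])@values
    if (cached)
      return(readNetworkGeoJSON(file.path(out,
                                          paste0("network_", tag,
                                                 "_attributed.geojson"))))
    net <- attributeReaches(ext$network, ext$filled, ext$flow, ext$acc,
                            rasters)
    writeNetworkGeoJSON(net, file.path(out, paste0("network_", tag,
                                                   "_attributed.geojson")))
    writeReachAttributes(net, file.path(out, paste0("reaches_", tag,
                                                    ".csv")))
    net
  }

  cal <- stage("extract_calibration",
               c("filled_calibration.asc", "network_calibration.geojson"),
               function(cached) extractOne(config$dem, "calibration",
                                           cached))
  calNet <- stage("attribute_calibration",
                  "network_calibration_attributed.geojson",
                  function(cached) attributeOne(cal, "calibration", cached))
  if (!is.null(config$receivingDem)) {
    rec <- stage("extract_receiving",
                 c("filled_receiving.asc", "network_receiving.geojson"),
                 function(cached) extractOne(config$receivingDem,
                                             "receiving", cached))
    recNet <- stage("attribute_receiving",
                    "network_receiving_attributed.geojson",
                    function(cached) attributeOne(rec, "receiving", cached))
  } else {
    rec <- cal; recNet <- calNet
  }

  predCols <- NULL
  if (!failed) {
    cand <- setdiff(names(calNet@reaches),
                    c("id", "segment", "fromNode", "toNode", "downstream",
                      "downRow", "downCol", "midRow", "midCol", "lengthKm",
                      "elevationM"))
    filt <- suppressWarnings(
      correlationFilter(calNet@reaches[, cand, drop = FALSE],
                        rMax = 0.7, priority = .predictorPriority(cand)))
    predCols <- names(filt)
    manifest$predictors <- list(kept = predCols,
                                dropped = attr(filt, "dropped"))
  }

  occAll <- if (!failed) readOccurrences(config$occurrences) else NULL
  suitMaps <- list(); binMaps <- list(); thresholds <- list()
  for (sp in config$species) {
    nm <- sp$name
    res <- stage(paste0("fit_", nm), paste0("model_", nm, ".json"),
                 function(cached) {
      occ <- occAll[occAll$species == nm, , drop = FALSE]
      occ <- cleanOccurrences(occ, cal$dem)
      presIds <- occurrenceReaches(occ, calNet)
      bgIds <- sampleBackground(occ, calNet, config$bufferKm,
                                config$nBackground, seed = config$seed)
      rdCal <- calNet@reaches
      pres <- rdCal[match(presIds, rdCal$id), predCols, drop = FALSE]
      bg <- rdCal[match(bgIds, rdCal$id), predCols, drop = FALSE]
      counts[[nm]] <<- c(presences = nrow(pres), background = nrow(bg))
      if (cached) {
        model <- readMaxEntModel(file.path(out,
                                           paste0("model_", nm, ".json")))
        return(list(model = model, pres = pres, candidates = NULL))
      }
      ev <- evaluateCandidates(
        pres, bg, regMultipliers = config$regMultipliers,
        classes = config$classes, E = config$E, alpha = config$alpha,
        k = min(config$folds, nrow(pres)), iterations = config$iterations,
        fraction = config$fraction, nKnots = config$nKnots,
        seed = config$seed)
      model <- ev$models[[paste0("m", ev$best$regMultiplier, "_",
                                 ev$best$classes)]]
      writeMaxEntModel(model, file.path(out, paste0("model_", nm, ".json")))
      utils::write.csv(ev$candidates,
                       file.path(out, paste0("candidates_", nm, ".csv")),
                       row.names = FALSE)
      list(model = model, pres = pres, candidates = ev$candidates,
           best = ev$best)
    })
    if (is.null(res)) next

    stage(paste0("transfer_", nm), paste0("suitability_", nm, ".csv"),
          function(cached) {
      rdRec <- recNet@reaches
      rows <- rdRec[, predCols, drop = FALSE]
      rownames(rows) <- rdRec$id
      sm <- predictSuitability(res$model, rows, species = nm)
      trainScores <- predictSuitability(res$model, res$pres)@value
      thr <- if (identical(sp$thresholdRule, "P10"))
        thresholdP10(trainScores) else thresholdMTP(trainScores)
      rule <- if (identical(sp$thresholdRule, "P10")) "P10" else "MTP"
      bm <- binarize(sm, thr, rule, network = "receiving")
      suitMaps[[nm]] <<- sm; binMaps[[nm]] <<- bm
      thresholds[[nm]] <<- list(rule = rule, value = thr)
      utils::write.csv(
        data.frame(reachId = as.integer(names(sm@value)),
                   raw = unname(sm@raw), suitability = unname(sm@value),
                   suitable = unname(bm@suitable)),
        file.path(out, paste0("suitability_", nm, ".csv")),
        row.names = FALSE)
      TRUE
    })
  }

  roles <- vapply(config$species, function(s) s$role, character(1))
  names(roles) <- vapply(config$species, function(s) s$name, character(1))
  natives <- names(roles)[roles == "native"]
  invaders <- names(roles)[roles == "invader"]
  if (length(natives) && length(invaders)) {
    stage("overlap", "overlap.json", function(cached) {
      ov <- lapply(natives, function(nat)
        habitatOverlap(binMaps[[nat]], binMaps[invaders], recNet))
      names(ov) <- natives
      groups <- lapply(binMaps, function(b)
        as.integer(names(b@suitable))[b@suitable])
      elev <- if (length(groups) >= 2 && all(lengths(groups) >= 2))
        elevationCompare(groups, recNet) else NULL
      summary <- list(overlap = ov, thresholds = thresholds,
                      suitableKm = lapply(binMaps, suitableLength,
                                          network = recNet),
                      elevation = elev)
      jsonlite::write_json(summary, file.path(out, "overlap.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      summary
    })
  }

  manifest$counts <- counts
  manifest$version <- as.character(utils::packageVersion("riverscape"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

#' Stable hash of a pipeline configuration
#' @param config config list.
#' @return md5 string of the canonicalized config.
#' @export
digestConfig <- function(config) {
  config <- config[order(names(config))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
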