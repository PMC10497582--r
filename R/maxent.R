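#' Clean species occurrence records
#'
#' Drops records with positional uncertainty above `maxUncertaintyM`, records
#' falling outside the grid (or on nodata cells), and duplicates within a
#' grid cell (first record kept). The drop report is attached as the
#' `dropReport` attribute.
#'
#' @param occ data.frame with columns `x`, `y`, `uncertainty_m` (and
#'   typically `species`, `source`).
#' @param grid an [ElevationGrid-class] in the occurrence CRS.
#' @param maxUncertaintyM uncertainty cutoff in m (default 100).
#' @return the cleaned data.frame; error when no record survives.
#' @export
cleanOccurrences <- function(occ, grid, maxUncertaintyM = 100) {
  stopifnot(all(c("x", "y", "uncertainty_m") %in% names(occ)))
  n0 <- nrow(occ)
  tooVague <- !is.na(occ$uncertainty_m) & occ$uncertainty_m > maxUncertaintyM
  occ1 <- occ[!tooVague, , drop = FALSE]

  cs <- grid@cellSize; org <- grid@origin
  d <- dim(grid@values)
  col <- ceiling((occ1$x - org[1]) / cs)
  row <- ceiling((org[2] - occ1$y) / cs)
  inside <- col >= 1 & col <= d[2] & row >= 1 & row <= d[1]
  onData <- inside
  onData[inside] <- !is.na(grid@values[cbind(row[inside], col[inside])])
  occ2 <- occ1[onData, , drop = FALSE]

  cell <- (col[onData] - 1) * d[1] + row[onData]
  dup <- duplicated(cell)
  out <- occ2[!dup, , drop = FALSE]
  out$row <- row[onData][!dup]
  out$col <- col[onData][!dup]
  if (!nrow(out)) stop("no usable occurrences")
  attr(out, "dropReport") <- c(input = n0, uncertain = sum(tooVague),
                               offGrid = sum(!onData), duplicate = sum(dup),
                               kept = nrow(out))
  out
}

#' Sample background reaches inside occurrence buffers
#'
#' The candidate pool is every reach whose polyline comes within `bufferKm`
#' of any occurrence (vertex-to-point distance; vertices are at most one
#' cell apart, so this matches geometric intersection to within a cell).
#' A seeded uniform sample is drawn without replacement when the pool is
#' large enough, with replacement otherwise.
#'
#' @param occ cleaned occurrence data.frame (`x`, `y`).
#' @param network a [StreamNetwork-class].
#' @param bufferKm buffer radius in km (> 0); no default, because the
#'   appropriate radius is study-specific.
#' @param nBackground background sample size (default 10000).
#' @param seed integer RNG seed.
#' @return integer vector of sampled reach ids, with the candidate pool in
#'   the `pool` attribute.
#' @export
sampleBackground <- function(occ, network, bufferKm, nBackground = 10000,
                             seed = 1) {
  stopifnot(bufferKm > 0, nrow(occ) >= 1)
  rad <- bufferKm * 1000
  geoms <- network@geometry
  ox <- occ$x; oy <- occ$y
  near <- vapply(geoms, function(g) {
    d2 <- outer(g[, 1], ox, "-")^2 + outer(g[, 2], oy, "-")^2
    min(d2) <= rad^2
  }, logical(1))
  pool <- network@reaches$id[near]
  if (!length(pool)) stop("no reach within the occurrence buffer")
  set.seed(seed)
  ids <- if (nBackground <= length(pool))
    sample(pool, nBackground, replace = FALSE)
  else sample(pool, nBackground, replace = TRUE)
  attr(ids, "pool") <- pool
  ids
}

#' Map occurrence records to their reaches
#'
#' Assigns each record to the nearest reach polyline (vertex distance) and
#' returns the distinct reach ids — the presence sample at reach resolution,
#' mirroring the per-cell deduplication of [cleanOccurrences()].
#'
#' @param occ occurrence data.frame (`x`, `y`).
#' @param network a [StreamNetwork-class].
#' @return integer vector of unique presence reach ids.
#' @export
occurrenceReaches <- function(occ, network) {
  unique(.nearestReach(occ$x, occ$y, network))
}

# Published MaxEnt per-class regularization betas, interpolated on the
# presence sample size (constant outside the table range).
.classBeta <- function(class, np) {
  interp <- function(xs, ys)
    stats::approx(xs, ys, xout = np, rule = 2)$y
  switch(class,
    linear = ,
    quadratic = ,
    product = interp(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
    hinge = 0.5,
    threshold = interp(c(0, 100), c(2, 1)),
    1)
}

# Per-feature L1 weights: class beta times the presence-sample spread of the
# feature (sd floored at 0.001 on the [0,1] feature scale) over sqrt(n).
.regWeights <- function(Fp, featureClass) {
  np <- nrow(Fp)
  sdj <- apply(Fp, 2, stats::sd)
  sdj <- pmax(sdj, 0.001)
  beta <- vapply(featureClass, .classBeta, numeric(1), np = np)
  beta * sdj / sqrt(np)
}

.logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a penalized maximum-entropy habitat model
#'
#' Maximizes the presence log-likelihood of the Gibbs distribution over the
#' background, `sum(beta' f_p) - n * log(sum_b exp(beta' f_b))`, minus the
#' L1 penalty `m * sum_j w_j |beta_j|`, with per-feature weights `w_j`
#' following the published MaxEnt class defaults (interpolated on presence
#' sample size and scaled by the feature spread). Optimization is FISTA
#' (accelerated proximal gradient with backtracking), which handles the
#' non-smooth penalty exactly and reproducibly.
#'
#' @param presence,background data.frames of raw predictor values.
#' @param spec a [FeatureExpansion-class]; normalizers are learned from the
#'   background when absent.
#' @param regMultiplier the regularization multiplier m (default 1).
#' @param tol convergence tolerance on the scaled proximal-gradient step
#'   (default 1e-7).
#' @param maxit iteration cap (default 5000); non-convergence is an error
#'   carrying the last gradient norm.
#' @param seed recorded in the model metadata (the fit itself is
#'   deterministic).
#' @return a [MaxEntModel-class].
#' @export
fitMaxent <- function(presence, background, spec = featureSpec("lq"),
                      regMultiplier = 1, tol = 1e-7, maxit = 5000,
                      seed = NA_integer_) {
  stopifnot(nrow(presence) >= 5)
  if (!length(spec@lower)) spec <- fitNormalizers(spec, background)
  Fp <- expandFeatures(presence, spec)
  Fb <- expandFeatures(background, spec)
  cl <- attr(Fp, "featureClass")
  w <- .regWeights(Fp, cl)
  lam <- regMultiplier * w
  np <- nrow(Fp); nb <- nrow(Fb)
  sp <- colSums(Fp)

  objective <- function(beta, eta) {
    np * .logSumExp(eta) - sum(sp * beta) + sum(lam * abs(beta))
  }
  smoothGrad <- function(eta) {
    q <- exp(eta - .logSumExp(eta))
    np * drop(crossprod(Fb, q)) - sp
  }

  # FISTA with adaptive (gradient-scheme) restart; the restart recovers
  # linear convergence on the ill-conditioned directions that correlated
  # features (e.g. a linear and its quadratic term) create.
  k <- ncol(Fb)
  beta <- numeric(k); y <- beta; tPrev <- 1
  step <- 4 / np          # features in [0,1] bound the curvature by ~np/4
  etaY <- drop(Fb %*% y)
  fY <- np * .logSumExp(etaY) - sum(sp * y)
  converged <- FALSE; gnorm <- NA_real_
  for (it in seq_len(min(maxit, 300L))) {
    g <- smoothGrad(etaY)
    repeat {
      cand <- sign(y - step * g) * pmax(abs(y - step * g) - step * lam, 0)
      etaC <- drop(Fb %*% cand)
      fC <- np * .logSumExp(etaC) - sum(sp * cand)
      dlt <- cand - y
      if (fC <= fY + sum(g * dlt) + sum(dlt^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-16) stop("line search failed; gradient norm ",
                             format(sqrt(sum(g^2))))
    }
    if (sum((y - cand) * (cand - beta)) > 0) {   # momentum restart
      tPrev <- 1
      yNew <- cand
    } else {
      tNew <- (1 + sqrt(1 + 4 * tPrev^2)) / 2
      yNew <- cand + ((tPrev - 1) / tNew) * (cand - beta)
      tPrev <- tNew
    }
    gnorm <- sqrt(sum(((beta - cand) / step)^2))
    moved <- sqrt(sum((cand - beta)^2))
    beta <- cand; y <- yNew
    etaY <- drop(Fb %*% y)
    fY <- np * .logSumExp(etaY) - sum(sp * y)
    if (moved / step < tol * np * max(1, sqrt(sum(beta^2)))) {
      converged <- TRUE
      break
    }
  }

  # Active-set Newton refinement: FISTA locates the support; a damped Newton
  # loop with KKT screening then drives the solution to high precision even
  # when correlated features leave the objective nearly flat.
  kktTol <- 1e-9 * np
  penObj <- function(b) {
    np * .logSumExp(drop(Fb %*% b)) - sum(sp * b) + sum(lam * abs(b))
  }
  fullGrad <- function(b) {
    eta <- drop(Fb %*% b)
    q <- exp(eta - .logSumExp(eta))
    list(g = np * drop(crossprod(Fb, q)) - sp, q = q)
  }
  newtonOK <- FALSE
  ridge <- 1e-8
  for (outer in seq_len(500)) {
    fg <- fullGrad(beta)
    g <- fg$g
    zero <- beta == 0
    viol <- zero & abs(g) > lam + kktTol
    activeOK <- !zero & abs(g + lam * sign(beta)) <= kktTol
    if (!any(viol) && all(activeOK[!zero])) { newtonOK <- TRUE; break }
    active <- which(!zero | viol)
    if (!length(active)) { newtonOK <- TRUE; break }
    s <- ifelse(beta[active] != 0, sign(beta[active]), -sign(g[active]))
    gA <- g[active] + lam[active] * s
    Fa <- Fb[, active, drop = FALSE]
    fa <- drop(crossprod(Fa, fg$q))
    H <- np * (crossprod(Fa, Fa * fg$q) - tcrossprod(fa))
    hScale <- max(diag(H), 1e-8)
    f0 <- penObj(beta)
    improved <- FALSE
    repeat {   # Levenberg-Marquardt damping around the Newton step
      Hd <- H
      diag(Hd) <- diag(Hd) + ridge * hScale
      d <- tryCatch(-solve(Hd, gA), error = function(e) NULL)
      if (is.null(d) || sum(d * gA) > 0) d <- -gA / hScale
      alpha <- 1
      for (ls in 1:30) {
        bNew <- beta
        bNew[active] <- beta[active] + alpha * d
        # a coefficient that crosses zero snaps to zero (leaves the set)
        crossed <- beta[active] != 0 & bNew[active] != 0 &
          sign(bNew[active]) != sign(beta[active])
        bNew[active][crossed] <- 0
        if (penObj(bNew) < f0 - 1e-14 * max(1, abs(f0))) {
          beta <- bNew; improved <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (improved) {
        ridge <- max(ridge / 10, 1e-10)
        break
      }
      ridge <- ridge * 100
      if (ridge > 1e8) break
    }
    if (!improved) break   # stalled: accept the current point if KKT-close
  }
  if (!newtonOK) {
    # accept a near-solution whose KKT residual is tiny relative to scale
    fg <- fullGrad(beta)
    g <- fg$g
    res <- ifelse(beta == 0, pmax(abs(g) - lam, 0),
                  abs(g + lam * sign(beta)))
    if (max(res) > 1e-4 * np)
      stop("maxent fit did not converge; KKT residual ", format(max(res)),
           " with proximal-gradient norm ", format(gnorm))
  }

  eta <- drop(Fb %*% beta)
  logZ <- .logSumExp(eta)
  q <- exp(eta - logZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  names(beta) <- colnames(Fb)
  names(lam) <- colnames(Fb)
  new("MaxEntModel", beta = beta, featureSpec = spec,
      regMultiplier = regMultiplier, regWeights = w, logZ = logZ,
      entropy = H,
      meta = list(nPresence = np, nBackground = nb, seed = seed,
                  iterations = it, proxGradNorm = gnorm))
}

#' Predict continuous suitability
#'
#' Raw values are the Gibbs densities `exp(beta' f - logZ)` (they sum to 1
#' over the training background). The default cloglog transform,
#' `1 - exp(-exp(H) * raw)`, maps them to the 0-1 suitability scale of the
#' reference MaxEnt release; the logistic transform is available behind the
#' flag. Both are strictly increasing in raw, so rankings are identical.
#'
#' @param model a [MaxEntModel-class].
#' @param rows data.frame of raw predictor values (training predictors must
#'   all be present).
#' @param transform `"cloglog"` (default) or `"logistic"`.
#' @param species label stored on the result.
#' @return a [SuitabilityMap-class]; values named by `rows` row names.
#' @export
predictSuitability <- function(model, rows, transform = c("cloglog",
                                                          "logistic"),
                               species = "species") {
  transform <- match.arg(transform)
  spec <- model@featureSpec
  missing <- setdiff(names(spec@lower), names(rows))
  if (length(missing))
    stop("missing predictors: ", paste(missing, collapse = ", "))
  FF <- suppressWarnings(expandFeatures(rows, spec))
  raw <- exp(drop(FF %*% model@beta[colnames(FF)]) - model@logZ)
  eh <- exp(model@entropy)
  val <- switch(transform,
                cloglog = 1 - exp(-eh * raw),
                logistic = eh * raw / (1 + eh * raw))
  nm <- rownames(rows)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(rows)))
  names(raw) <- nm; names(val) <- nm
  new("SuitabilityMap", raw = raw, value = val, transform = transform,
      species = species)
}

#' Serialize a fitted model to JSON
#' @param model a [MaxEntModel-class].
#' @param path output file.
#' @export
writeMaxEntModel <- function(model, path) {
  spec <- model@featureSpec
  obj <- list(beta = as.list(model@beta),
              classes = spec@classes, nKnots = spec@nKnots,
              lower = as.list(spec@lower), upper = as.list(spec@upper),
              regMultiplier = model@regMultiplier,
              regWeights = as.list(model@regWeights),
              logZ = model@logZ, entropy = model@entropy,
              meta = model@meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model
#' @param path JSON file written by [writeMaxEntModel()].
#' @return a [MaxEntModel-class].
#' @export
readMaxEntModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- new("FeatureExpansion", classes = obj$classes,
              nKnots = obj$nKnots, lower = unlist(obj$lower),
              upper = unlist(obj$upper))
  new("MaxEntModel", beta = unlist(obj$beta), featureSpec = spec,
      regMultiplier = obj$regMultiplier, regWeights = unlist(obj$regWeights),
      logZ = obj$logZ, entropy = obj$entropy,
      meta = as.list(obj$meta))
}
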