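#' Seeded k-fold partition of presences
#'
#' @param n number of presence records.
#' @param k folds (default 10).
#' @param seed integer RNG seed.
#' @return integer fold labels (1..k) of length `n`, sizes differing by at
#'   most one.
#' @export
kfoldSplit <- function(n, k = 10, seed = 1) {
  if (n < k) stop("fewer presences (", n, ") than folds (", k,
                  "); use a smaller k")
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# model curve points over unique score thresholds:
# x = proportion of background predicted present, y = sensitivity
.rocPoints <- function(pres, bg) {
  t <- sort(unique(c(pres, bg)), decreasing = TRUE)
  x <- .fracAtLeast(bg, t)
  y <- .fracAtLeast(pres, t)
  list(thresholds = t, x = c(0, x), y = c(0, y))
}

# fraction of `scores` >= each threshold (thresholds sorted decreasing)
.fracAtLeast <- function(scores, thresholds) {
  s <- sort(scores)
  below <- findInterval(thresholds, s, left.open = TRUE)  # count of s < t
  (length(s) - below) / length(s)
}

# partial AUC ratio above sensitivity 1 - E (trapezoid on the point curve,
# random expectation = area under the diagonal over the same x range)
.pAUCratio <- function(x, y, E) {
  sens0 <- 1 - E
  i <- which(y >= sens0 - 1e-12)[1]
  if (is.na(i)) return(NA_real_)
  if (i > 1 && y[i] > sens0) {
    f <- (sens0 - y[i - 1]) / (y[i] - y[i - 1])
    x0 <- x[i - 1] + f * (x[i] - x[i - 1]); y0 <- sens0
  } else { x0 <- x[i]; y0 <- y[i] }
  xs <- c(x0, x[seq(i, length(x))], 1)
  ys <- c(y0, y[seq(i, length(y))], 1)
  keep <- !duplicated(paste(xs, ys))
  xs <- xs[keep]; ys <- ys[keep]
  aMod <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  aRand <- (1 - x0^2) / 2
  if (aRand <= 0) return(NA_real_)
  aMod / aRand
}

#' Partial-ROC evaluation
#'
#' Bootstrap partial-AUC ratios over the low-omission region: per replicate,
#' `fraction` of the test presences are resampled with replacement, the
#' partial area under the sensitivity versus proportion-predicted-present
#' curve is taken over sensitivities above `1 - E`, and divided by the same
#' partial area under the random-expectation diagonal. A mean ratio of 1
#' is random-equivalent performance; values near 2 indicate strong
#' discrimination. The p-value is the proportion of replicates with ratio
#' at most 1.
#'
#' @param presScores suitability scores at test presences (>= 10 advised).
#' @param bgScores suitability scores at background reaches.
#' @param E acceptable omission proportion (default 0.05).
#' @param iterations bootstrap replicates (default 500).
#' @param fraction resampled share of test presences (default 0.5).
#' @param seed integer RNG seed.
#' @return list with `aucRatioMean`, `pValue`, and the replicate `ratios`.
#' @export
partialROC <- function(presScores, bgScores, E = 0.05, iterations = 500,
                       fraction = 0.5, seed = 1) {
  stopifnot(length(presScores) >= 1, length(bgScores) >= 1,
            E > 0, E < 0.5, iterations >= 1, fraction > 0, fraction <= 1)
  if (length(unique(c(presScores, bgScores))) == 1) {
    warning("all scores identical: no discrimination, AUC ratio set to 1")
    return(list(aucRatioMean = 1, pValue = 1,
                ratios = rep(1, iterations)))
  }
  pts <- .rocPoints(presScores, bgScores)
  t <- pts$thresholds
  nres <- max(1L, ceiling(fraction * length(presScores)))
  set.seed(seed)
  ratios <- vapply(seq_len(iterations), function(b) {
    res <- sample(presScores, nres, replace = TRUE)
    y <- c(0, .fracAtLeast(res, t))
    .pAUCratio(pts$x, y, E)
  }, numeric(1))
  ratios <- ratios[is.finite(ratios)]
  list(aucRatioMean = mean(ratios), pValue = mean(ratios <= 1),
       ratios = ratios)
}

#' Omission rate at a threshold
#'
#' Proportion of test presences scoring strictly below the threshold (scores
#' equal to the threshold count as predicted present, matching the
#' binarization tie rule).
#'
#' @param scores suitability scores at test presences.
#' @param threshold binarization threshold.
#' @return proportion in [0, 1].
#' @export
omissionRate <- function(scores, threshold) {
  if (!length(scores)) stop("empty test set")
  mean(scores < threshold)
}

#' Small-sample corrected AIC of a fitted model
#'
#' The presence log-likelihood uses the raw Gibbs densities (normalized to
#' sum to 1 over the training background); parameters are the non-zero
#' coefficients. `AICc = -2 LL + 2k + 2k(k+1)/(n-k-1)`; candidates with
#' `n <= k + 1` are reported as `Inf` (excluded).
#'
#' @param model a [MaxEntModel-class].
#' @param presence data.frame of presence predictor rows.
#' @return the AICc value (possibly `Inf`).
#' @export
aicc <- function(model, presence) {
  FF <- suppressWarnings(expandFeatures(presence, model@featureSpec))
  ll <- sum(drop(FF %*% model@beta[colnames(FF)]) - model@logZ)
  k <- sum(abs(model@beta) > 0)
  n <- nrow(presence)
  if (n <= k + 1) return(Inf)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select the best candidate model
#'
#' Filters to statistically significant candidates (partial-ROC p below
#' `alpha`), then to those meeting the omission criterion
#' (`omissionRate <= E`); among these the minimum-AICc candidate wins, ties
#' broken by fewer parameters, then lower regularization multiplier. If the
#' omission filter empties the set, the significant candidate with minimal
#' omission is returned, flagged via the `omissionRelaxed` attribute.
#'
#' @param candidates data.frame with columns `regMultiplier`, `classes`,
#'   `procAucMean`, `procPValue`, `omissionRate`, `aicc`, `nParameters`.
#' @param E acceptable omission proportion (default 0.05).
#' @param alpha significance level for partial ROC (default 0.05).
#' @return the selected row (one-row data.frame with `deltaAicc` over the
#'   significant set).
#' @export
selectBest <- function(candidates, E = 0.05, alpha = 0.05) {
  stopifnot(nrow(candidates) >= 1)
  sig <- candidates[!is.na(candidates$procPValue) &
                      candidates$procPValue < alpha, , drop = FALSE]
  if (!nrow(sig)) stop("no admissible model: no candidate is significant")
  sig$deltaAicc <- sig$aicc - min(sig$aicc)
  ok <- sig[sig$omissionRate <= E, , drop = FALSE]
  relaxed <- FALSE
  if (!nrow(ok)) {
    ok <- sig[sig$omissionRate == min(sig$omissionRate), , drop = FALSE]
    relaxed <- TRUE
  }
  ord <- order(ok$aicc, ok$nParameters, ok$regMultiplier)
  out <- ok[ord[1], , drop = FALSE]
  attr(out, "omissionRelaxed") <- relaxed
  out
}

#' Evaluate a candidate-model grid with k-fold cross-validation
#'
#' For every (regularization multiplier, feature classes) pair: the model is
#' fitted on all presences (for AICc, parameter counts, and the final
#' predictor), and k-fold cross-validated so that each presence is scored by
#' the model not trained on it. Partial ROC compares the pooled held-out
#' presence scores with the fold-averaged background scores; the omission
#' rate compares them with the E-quantile threshold of the full-model
#' training scores.
#'
#' @param presence,background data.frames of raw predictor values.
#' @param regMultipliers numeric vector of multipliers.
#' @param classes character vector of feature-class strings (e.g. "l","lq").
#' @param E,alpha evaluation constants (defaults 0.05).
#' @param k folds (default 10).
#' @param iterations,fraction partial-ROC bootstrap settings.
#' @param nKnots hinge/threshold knots.
#' @param seed integer RNG seed.
#' @return list: `candidates` (data.frame, one row each), `models` (full-data
#'   fits, named `m<multiplier>_<classes>`), `best` (from [selectBest()]).
#' @export
evaluateCandidates <- function(presence, background,
                               regMultipliers = c(0.5, 1, 2),
                               classes = c("l", "lq", "lqh"),
                               E = 0.05, alpha = 0.05, k = 10,
                               iterations = 500, fraction = 0.5,
                               nKnots = 50, seed = 1) {
  n <- nrow(presence)
  folds <- kfoldSplit(n, k, seed)
  grid <- expand.grid(regMultiplier = regMultipliers, classes = classes,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid)); models <- list()
  for (g in seq_len(nrow(grid))) {
    rm_ <- grid$regMultiplier[g]; cls <- grid$classes[g]
    spec <- featureSpec(cls, nKnots)
    full <- fitMaxent(presence, background, spec, regMultiplier = rm_,
                      seed = seed)
    cvPres <- numeric(n)
    bgMat <- matrix(NA_real_, nrow(background), k)
    for (f in seq_len(k)) {
      tr <- presence[folds != f, , drop = FALSE]
      te <- which(folds == f)
      mf <- fitMaxent(tr, background, spec, regMultiplier = rm_,
                      seed = seed)
      cvPres[te] <- predictSuitability(mf, presence[te, , drop = FALSE])@value
      bgMat[, f] <- predictSuitability(mf, background)@value
    }
    bgScore <- rowMeans(bgMat)      # fold-averaged prediction (cloglog scale)
    proc <- partialROC(cvPres, bgScore, E = E, iterations = iterations,
                       fraction = fraction, seed = seed)
    trainScores <- predictSuitability(full, presence)@value
    thrE <- sort(trainScores)[ceiling(E * n)]
    om <- omissionRate(cvPres, thrE)
    rows[[g]] <- data.frame(
      regMultiplier = rm_, classes = cls,
      procAucMean = proc$aucRatioMean, procPValue = proc$pValue,
      omissionRate = om, aicc = aicc(full, presence),
      nParameters = sum(abs(full@beta) > 0))
    models[[paste0("m", rm_, "_", cls)]] <- full
  }
  candidates <- do.call(rbind, rows)
  best <- selectBest(candidates, E = E, alpha = alpha)
  list(candidates = candidates, models = models, best = best)
}
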