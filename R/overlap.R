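#' Minimum-training-presence threshold
#'
#' The smallest suitability over the training presences; binarizing at it
#' (with the >= tie rule) gives exactly zero training omission. Appropriate
#' for well-curated occurrence data.
#'
#' @param trainScores suitability at training presences.
#' @return the threshold.
#' @export
thresholdMTP <- function(trainScores) {
  if (!length(trainScores)) stop("empty training scores")
  min(trainScores)
}

#' Ten-percentile training presence threshold
#'
#' The `ceiling(0.1 n)`-th smallest training score, leaving up to a 10%
#' omission margin for the least-suitable training records — the usual choice
#' when part of the occurrence data is of mixed provenance. Warns below 10
#' training presences.
#'
#' @param trainScores suitability at training presences.
#' @return the threshold.
#' @export
thresholdP10 <- function(trainScores) {
  n <- length(trainScores)
  if (!n) stop("empty training scores")
  if (n < 10) warning("fewer than 10 training presences; P10 is coarse")
  sort(trainScores)[ceiling(0.1 * n)]
}

#' Binarize a suitability map
#'
#' A reach is suitable iff its continuous suitability is `>=` the threshold
#' (ties count as suitable, which guarantees zero training omission at the
#' MTP threshold).
#'
#' @param map a [SuitabilityMap-class].
#' @param threshold binarization threshold.
#' @param rule rule tag, `"MTP"` or `"P10"`.
#' @param network free-text network identifier.
#' @return a [BinaryMap-class].
#' @export
binarize <- function(map, threshold, rule = c("MTP", "P10"),
                     network = "network") {
  rule <- match.arg(rule)
  stopifnot(is(map, "SuitabilityMap"))
  new("BinaryMap", suitable = map@value >= threshold, threshold = threshold,
      rule = rule, species = map@species, network = network)
}

#' Total suitable stream length
#'
#' @param binary a [BinaryMap-class] whose names are reach ids.
#' @param network the matching [StreamNetwork-class].
#' @return total length of suitable reaches in km.
#' @export
suitableLength <- function(binary, network) {
  rd <- network@reaches
  ids <- as.integer(names(binary@suitable))
  idx <- match(ids, rd$id)
  if (anyNA(idx)) stop("reach ids in the map do not match the network")
  sum(rd$lengthKm[idx[binary@suitable]])
}

#' Habitat overlap between a native and one or more invader maps
#'
#' The headline statistic is the percentage of native-suitable reaches that
#' are also suitable for the invader (native denominator, so the percentage
#' is asymmetric); shared lengths in km are symmetric and reported alongside.
#' With several invaders, the union variant counts native reaches suitable
#' for at least one of them.
#'
#' @param native a [BinaryMap-class].
#' @param invaders a [BinaryMap-class] or list of them (same network and
#'   reach ids).
#' @param network the shared [StreamNetwork-class].
#' @return list: `pairs` (data.frame per invader: suitable lengths, shared
#'   length, percent overlap by reach count and by length) and `union`
#'   (percent of native-suitable reaches overlapped by any invader, with
#'   lengths). Percent is `NA` (flagged by a warning) when the native map
#'   has no suitable reach.
#' @export
habitatOverlap <- function(native, invaders, network) {
  if (is(invaders, "BinaryMap")) invaders <- list(invaders)
  rd <- network@reaches
  ids <- names(native@suitable)
  idx <- match(as.integer(ids), rd$id)
  if (anyNA(idx)) stop("reach ids do not match the network")
  len <- rd$lengthKm[idx]
  natSel <- native@suitable
  nNat <- sum(natSel)
  if (nNat == 0) warning("native map has no suitable reach; percent is NA")

  anyInv <- rep(FALSE, length(natSel))
  pairs <- lapply(invaders, function(inv) {
    stopifnot(identical(names(inv@suitable), ids))
    sel <- inv@suitable
    anyInv <<- anyInv | sel
    shared <- natSel & sel
    data.frame(
      native = native@species, invader = inv@species,
      nativeKm = sum(len[natSel]), invaderKm = sum(len[sel]),
      sharedKm = sum(len[shared]),
      percentReaches = if (nNat) 100 * sum(shared) / nNat else NA_real_,
      percentLength = if (sum(len[natSel]) > 0)
        100 * sum(len[shared]) / sum(len[natSel]) else NA_real_)
  })
  shared <- natSel & anyInv
  union <- data.frame(
    native = native@species, invader = "any",
    nativeKm = sum(len[natSel]), invaderKm = sum(len[anyInv]),
    sharedKm = sum(len[shared]),
    percentReaches = if (nNat) 100 * sum(shared) / nNat else NA_real_,
    percentLength = if (sum(len[natSel]) > 0)
      100 * sum(len[shared]) / sum(len[natSel]) else NA_real_)
  list(pairs = do.call(rbind, pairs), union = union)
}

#' Compare reach elevations between suitability categories
#'
#' Per-reach elevation is the DEM value at the reach midpoint. Three or more
#' groups are compared with the Kruskal-Wallis rank-sum test; exactly two
#' with the Wilcoxon (Mann-Whitney) rank-sum test. All pairwise Wilcoxon
#' tests are reported alongside the global test.
#'
#' @param groups named list of reach-id vectors.
#' @param network an attributed [StreamNetwork-class] (needs `elevationM`).
#' @return list: `means` (group mean elevations), `global` (test name,
#'   statistic, p), `pairwise` (data.frame of pair, W statistic, p).
#' @export
elevationCompare <- function(groups, network) {
  stopifnot(length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("singleton group: need >= 2 reaches")
  rd <- network@reaches
  if (!"elevationM" %in% names(rd))
    stop("network lacks elevation attributes; run attributeReaches()")
  elev <- lapply(groups, function(g) {
    idx <- match(g, rd$id)
    if (anyNA(idx)) stop("unknown reach ids in group")
    rd$elevationM[idx]
  })
  vals <- unlist(elev)
  fac <- factor(rep(names(elev), lengths(elev)), levels = names(elev))
  global <- if (length(groups) >= 3) {
    kw <- stats::kruskal.test(vals, fac)
    list(test = "kruskal-wallis", statistic = unname(kw$statistic),
         pValue = kw$p.value)
  } else {
    wt <- stats::wilcox.test(elev[[1]], elev[[2]], exact = FALSE)
    list(test = "wilcoxon", statistic = unname(wt$statistic),
         pValue = wt$p.value)
  }
  prs <- utils::combn(names(elev), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
    a <- prs[1, j]; b <- prs[2, j]
    wt <- stats::wilcox.test(elev[[a]], elev[[b]], exact = FALSE)
    data.frame(groupA = a, groupB = b, W = unname(wt$statistic),
               pValue = wt$p.value)
  }))
  list(means = vapply(elev, mean, numeric(1)), global = global,
       pairwise = pairwise)
}
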