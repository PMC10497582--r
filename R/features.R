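#' Construct a feature expansion specification
#'
#' Feature classes follow the MaxEnt conventions: `linear` (min-max scaled
#' value), `quadratic` (its square), `product` (pairwise products), `hinge`
#' (forward and reverse piecewise ramps at `nKnots` knots) and `threshold`
#' (step indicators). Class strings such as `"lqph"` are accepted as
#' shorthand (l, q, p, h, t).
#'
#' @param classes character vector of class names, or a compact string like
#'   `"lqh"`.
#' @param nKnots hinge/threshold knots per variable (default 50).
#' @return a [FeatureExpansion-class] (normalizers unset).
#' @export
featureSpec <- function(classes = "lq", nKnots = 50) {
  if (length(classes) == 1 && !classes %in%
      c("linear", "quadratic", "product", "hinge", "threshold")) {
    map <- c(l = "linear", q = "quadratic", p = "product", h = "hinge",
             t = "threshold")
    letters1 <- strsplit(classes, "")[[1]]
    if (!all(letters1 %in% names(map)))
      stop("unknown feature class letters in '", classes, "'")
    classes <- unname(map[letters1])
  }
  new("FeatureExpansion", classes = unique(classes), nKnots = nKnots,
      lower = numeric(), upper = numeric())
}

#' Default feature classes by presence sample size
#'
#' The MaxEnt auto-feature convention: fewer than 10 presences use linear
#' only; 10-14 add quadratic; 15-79 add hinge; 80 and more add product.
#'
#' @param nPresence number of presence records.
#' @return a class string accepted by [featureSpec()].
#' @export
autoFeatureClasses <- function(nPresence) {
  if (nPresence < 10) "l"
  else if (nPresence < 15) "lq"
  else if (nPresence < 80) "lqh"
  else "lqph"
}

#' Learn min-max normalizers from the background
#'
#' @param spec a [FeatureExpansion-class].
#' @param background data.frame of raw background predictor values.
#' @return the spec with per-variable lower/upper bounds filled.
#' @export
fitNormalizers <- function(spec, background) {
  stopifnot(is(spec, "FeatureExpansion"), nrow(background) > 0)
  num <- vapply(background, is.numeric, logical(1))
  vars <- names(background)[num]
  spec@lower <- vapply(background[vars], min, numeric(1), na.rm = TRUE)
  spec@upper <- vapply(background[vars], max, numeric(1), na.rm = TRUE)
  spec
}

#' Expand raw predictor rows into the MaxEnt design matrix
#'
#' Values are min-max scaled with the background normalizers (clamped to
#' [0, 1] outside the training range, the MaxEnt transfer convention), then
#' expanded per the enabled classes. Column order is deterministic:
#' variables in normalizer order, classes in linear, quadratic, product,
#' forward hinge, reverse hinge, threshold order, knots ascending.
#' Degenerate variables (background max = min) contribute no features and
#' raise a warning.
#'
#' @param rows data.frame of raw predictor values.
#' @param spec a fitted [FeatureExpansion-class] (see [fitNormalizers()]).
#' @return numeric design matrix, all entries in [0, 1].
#' @export
expandFeatures <- function(rows, spec) {
  stopifnot(is(spec, "FeatureExpansion"))
  if (!length(spec@lower)) stop("normalizers not fitted; see fitNormalizers()")
  vars <- names(spec@lower)
  if (!all(vars %in% names(rows)))
    stop("missing predictors: ",
         paste(setdiff(vars, names(rows)), collapse = ", "))
  degen <- spec@upper - spec@lower <= 0
  if (any(degen)) {
    warning("degenerate predictors dropped from features: ",
            paste(vars[degen], collapse = ", "))
    vars <- vars[!degen]
  }
  n <- nrow(rows)
  V <- vapply(vars, function(v) {
    s <- (rows[[v]] - spec@lower[[v]]) / (spec@upper[[v]] - spec@lower[[v]])
    pmin(pmax(s, 0), 1)
  }, numeric(n))
  V <- matrix(V, nrow = n, dimnames = list(NULL, vars))

  cols <- list(); cl <- character()
  add <- function(m, names, class) {
    cols[[length(cols) + 1L]] <<- m
    colnames(cols[[length(cols)]]) <<- names
    cl <<- c(cl, rep(class, length(names)))
  }
  if ("linear" %in% spec@classes && length(vars))
    add(V, paste0("l_", vars), "linear")
  if ("quadratic" %in% spec@classes && length(vars))
    add(V^2, paste0("q_", vars), "quadratic")
  if ("product" %in% spec@classes && length(vars) >= 2) {
    pr <- utils::combn(vars, 2)
    m <- apply(pr, 2, function(p) V[, p[1]] * V[, p[2]])
    m <- matrix(m, nrow = n)
    add(m, paste0("p_", pr[1, ], ".", pr[2, ]), "product")
  }
  if ("hinge" %in% spec@classes && length(vars)) {
    kf <- seq(0, 1, length.out = spec@nKnots + 1)[-(spec@nKnots + 1)]
    kr <- seq(0, 1, length.out = spec@nKnots + 1)[-1]
    for (v in vars) {
      m <- vapply(kf, function(k) pmax(0, (V[, v] - k) / (1 - k)),
                  numeric(n))
      add(matrix(m, nrow = n),
          sprintf("hf_%s_%03d", v, seq_along(kf)), "hinge")
    }
    for (v in vars) {
      m <- vapply(kr, function(k) pmax(0, (k - V[, v]) / k), numeric(n))
      add(matrix(m, nrow = n),
          sprintf("hr_%s_%03d", v, seq_along(kr)), "hinge")
    }
  }
  if ("threshold" %in% spec@classes && length(vars)) {
    kt <- seq(0, 1, length.out = spec@nKnots + 2)
    kt <- kt[-c(1, length(kt))]
    for (v in vars) {
      m <- vapply(kt, function(k) as.numeric(V[, v] > k), numeric(n))
      add(matrix(m, nrow = n),
          sprintf("t_%s_%03d", v, seq_along(kt)), "threshold")
    }
  }
  if (!length(cols)) stop("feature expansion produced no features")
  out <- do.call(cbind, cols)
  attr(out, "featureClass") <- cl
  out
}
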