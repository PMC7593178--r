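# Maxent-style feature expansion: linear, quadratic, product and hinge
# transformations of the covariates, min-max scaled to [0, 1] on the
# training ranges.  The feature map built at training time is reused at
# prediction time with covariates clamped to the training ranges.

#' Expand covariates into Maxent-style features
#'
#' Feature classes: \code{l} linear (x), \code{q} quadratic (x^2),
#' \code{p} product (all pairwise x_a * x_b, a < b), \code{h} hinge —
#' forward \eqn{\max(0, x - t) / (max - t)} and reverse
#' \eqn{\max(0, t - x) / (t - min)} at \code{nKnots} knots per variable
#' and direction, placed at equally spaced empirical quantiles of the
#' combined presence + contrast values.  Every hinge column runs from 0
#' at one end of the training range to 1 at the other; l/q/p columns are
#' min-max scaled to [0, 1] using the training column ranges, which are
#' stored in the feature map for clamped reuse at prediction.
#'
#' @param x an \linkS4class{SWD} or data.frame of covariates.
#' @param classes feature-class string, a subset of "lqph".
#' @param nKnots hinge knots per variable per direction (default 20).
#' @return list with \code{matrix} (records x features) and \code{map},
#'   a data.frame describing each feature (kind, var, var2, knot,
#'   denom, cmin, cmax) plus a \code{ranges} attribute with per-variable
#'   training min/max.
#' @export
expandFeatures <- function(x, classes = "lqph", nKnots = 20) {
  df <- if (is(x, "SWD")) x@data else as.data.frame(x)
  cls <- strsplit(classes, "")[[1L]]
  if (length(cls) == 0L) stop("feature-class string must be nonempty")
  bad <- setdiff(cls, c("l", "q", "p", "h"))
  if (length(bad))
    stop("unknown feature class letter(s): ", paste(bad, collapse = ", "))
  vars <- colnames(df)
  ranges <- data.frame(variable = vars,
                       min = vapply(df, min, 0, na.rm = TRUE),
                       max = vapply(df, max, 0, na.rm = TRUE),
                       row.names = NULL)
  map <- list()
  add <- function(kind, var, var2 = NA_character_, knot = NA_real_,
                  denom = NA_real_) {
    map[[length(map) + 1L]] <<- data.frame(
      kind = kind, var = var, var2 = var2, knot = knot, denom = denom,
      cmin = NA_real_, cmax = NA_real_)
  }
  if ("l" %in% cls) for (v in vars) add("linear", v)
  if ("q" %in% cls) for (v in vars) add("quadratic", v)
  if ("p" %in% cls && length(vars) >= 2L)
    for (a in seq_len(length(vars) - 1L))
      for (b in (a + 1L):length(vars))
        add("product", vars[a], vars[b])
  if ("h" %in% cls) {
    for (v in vars) {
      lo <- ranges$min[ranges$variable == v]
      hi <- ranges$max[ranges$variable == v]
      fwd <- stats::quantile(df[[v]], probs = (0:(nKnots - 1L)) / nKnots,
                             na.rm = TRUE, names = FALSE, type = 7)
      rev_ <- stats::quantile(df[[v]], probs = (1:nKnots) / nKnots,
                              na.rm = TRUE, names = FALSE, type = 7)
      for (t in fwd) add("hinge_fwd", v, knot = t, denom = hi - t)
      for (t in rev_) add("hinge_rev", v, knot = t, denom = t - lo)
    }
  }
  map <- do.call(rbind, map)
  mat <- .featureColumns(map, df)
  # training column ranges for min-max scaling of l/q/p columns
  scaleKinds <- map$kind %in% c("linear", "quadratic", "product")
  map$cmin <- ifelse(scaleKinds, apply(mat, 2L, min), 0)
  map$cmax <- ifelse(scaleKinds, apply(mat, 2L, max), 1)
  mat <- .scaleColumns(mat, map)
  attr(map, "ranges") <- ranges
  list(matrix = mat, map = map)
}

# raw (unscaled) feature columns from a map
.featureColumns <- function(map, df) {
  n <- nrow(df)
  mat <- matrix(0, n, nrow(map))
  for (j in seq_len(nrow(map))) {
    f <- map[j, ]
    mat[, j] <- switch(f$kind,
      linear = df[[f$var]],
      quadratic = df[[f$var]]^2,
      product = df[[f$var]] * df[[f$var2]],
      hinge_fwd = if (f$denom > 0)
        pmax(0, df[[f$var]] - f$knot) / f$denom else rep(0, n),
      hinge_rev = if (f$denom > 0)
        pmax(0, f$knot - df[[f$var]]) / f$denom else rep(0, n),
      stop("unknown feature kind: ", f$kind))
  }
  colnames(mat) <- featureNames(map)
  mat
}

.scaleColumns <- function(mat, map) {
  for (j in seq_len(nrow(map))) {
    if (map$kind[j] %in% c("linear", "quadratic", "product")) {
      rng <- map$cmax[j] - map$cmin[j]
      mat[, j] <- if (rng > 0) (mat[, j] - map$cmin[j]) / rng else 0
    }
    # clip: new data inside the clamped variable range can still fall
    # outside a derived column's training range (e.g. x^2 near 0)
    mat[, j] <- pmin(pmax(mat[, j], 0), 1)
  }
  mat
}

featureNames <- function(map) {
  vapply(seq_len(nrow(map)), function(j) {
    f <- map[j, ]
    switch(f$kind,
      linear = paste0("l_", f$var),
      quadratic = paste0("q_", f$var),
      product = paste0("p_", f$var, "_", f$var2),
      hinge_fwd = sprintf("hf_%s_%.6g", f$var, f$knot),
      hinge_rev = sprintf("hr_%s_%.6g", f$var, f$knot))
  }, "")
}

# evaluate a stored feature map on new data, clamping covariates to the
# training variable ranges first
applyFeatureMap <- function(map, ranges, df) {
  for (i in seq_len(nrow(ranges))) {
    v <- ranges$variable[i]
    df[[v]] <- pmin(pmax(df[[v]], ranges$min[i]), ranges$max[i])
  }
  .scaleColumns(.featureColumns(map, df), map)
}
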