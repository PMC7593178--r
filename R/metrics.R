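# Evaluation metrics: AUC (rank-based Mann-Whitney), TSS (exhaustive
# threshold scan), AICc (Maxent-style models only), plus threshold
# selection for binary maps and model-level evaluation with hold-out or
# k-fold validation.

#' AUC from presence and contrast scores
#'
#' Rank-based Mann-Whitney estimate: the mean over all presence-contrast
#' pairs of 1 (presence scores higher), 0.5 (tie), 0.
#'
#' @param presence,contrast numeric score vectors (both nonempty).
#' @return AUC in [0, 1].
#' @export
aucFromScores <- function(presence, contrast) {
  if (!length(presence) || !length(contrast))
    stop("both score vectors must be nonempty")
  r <- rank(c(presence, contrast), ties.method = "average")
  np <- length(presence); nc <- length(contrast)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nc)
}

#' TSS from presence and contrast scores
#'
#' True skill statistic: sensitivity + specificity - 1 under the rule
#' "score >= t predicts presence", maximized exactly over all distinct
#' observed scores.  Ties between thresholds break toward the highest
#' sensitivity, then the lowest threshold.
#'
#' @param presence,contrast numeric score vectors (both nonempty).
#' @return list(tss, threshold).
#' @export
tssFromScores <- function(presence, contrast) {
  if (!length(presence) || !length(contrast))
    stop("both score vectors must be nonempty")
  cand <- sort(unique(c(presence, contrast)))
  sens <- vapply(cand, function(t) mean(presence >= t), 0)
  spec <- vapply(cand, function(t) mean(contrast < t), 0)
  tss <- sens + spec - 1
  best <- which(tss == max(tss))
  best <- best[sens[best] == max(sens[best])]
  best <- best[1L]  # candidates are sorted: first = lowest threshold
  list(tss = tss[best], threshold = cand[best])
}

#' AICc value from counts and log-likelihood
#'
#' \eqn{AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)}; returns NA (the
#' undefined marker) when \eqn{n - k - 1 \le 0}.
#'
#' @param k number of parameters (non-zero coefficients).
#' @param lnL log-likelihood.
#' @param n sample size (number of presences).
#' @return the AICc, or NA when undefined.
#' @export
aiccValue <- function(k, lnL, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc of a Maxent-style model
#'
#' k counts the non-zero fitted feature coefficients (intercept
#' excluded); the log-likelihood sums, over the presence records of the
#' full (unpartitioned) table, the log of the raw score normalized to
#' sum 1 over the evaluation extent — all finite cells of
#' \code{extent} when a raster stack is given, otherwise the table's
#' background records.
#'
#' @param model a Maxent-style \linkS4class{TrainedSDM}.
#' @param x the full \linkS4class{SWD} (all observation locations).
#' @param extent optional \linkS4class{GridStack} covering the study
#'   area.
#' @return the AICc, or NA when n - k - 1 <= 0 (undefined, flagged via
#'   a message, not an error).
#' @export
aicc <- function(model, x = model@swd, extent = NULL) {
  if (model@method != "ME")
    stop("AICc is supported for the Maxent-style method only")
  k <- sum(model@coefs[-1L] != 0)
  n <- nPresence(x)
  rawPres <- predict(model, swdSubset(x, records = which(x@pa == 1L)),
                     type = "raw")
  tot <- if (!is.null(extent)) {
    r <- predictRaster(model, extent, type = "raw")
    sum(r[is.finite(r)])
  } else {
    sum(predict(model, swdSubset(x, records = which(x@pa == 0L)),
                type = "raw"))
  }
  lnL <- sum(log(rawPres / tot))
  out <- aiccValue(k, lnL, n)
  if (is.na(out))
    message("AICc undefined: n - k - 1 <= 0 (n = ", n, ", k = ", k, ")")
  out
}

#' Select a classification threshold
#'
#' Rules: \code{"max_tss"} — the TSS-maximizing threshold;
#' \code{"equal_sens_spec"} — the observed score minimizing
#' |sensitivity - specificity| (smallest qualifying score on ties);
#' \code{"min_training_presence"} — the minimum presence score.
#'
#' @param presence,contrast numeric score vectors.
#' @param rule threshold rule.
#' @return the selected threshold.
#' @export
selectThreshold <- function(presence, contrast,
                            rule = c("max_tss", "equal_sens_spec",
                                     "min_training_presence")) {
  rule <- match.arg(rule)
  switch(rule,
    max_tss = tssFromScores(presence, contrast)$threshold,
    min_training_presence = min(presence),
    equal_sens_spec = {
      cand <- sort(unique(c(presence, contrast)))
      gap <- vapply(cand, function(t)
        abs(mean(presence >= t) - mean(contrast < t)), 0)
      cand[which.min(gap)]  # which.min takes the first = smallest score
    })
}

# metric value of a model on a table (higher-is-better metrics only)
.scoreMetric <- function(model, x, metric) {
  sc <- predict(model, x)
  p <- sc[x@pa == 1L]; b <- sc[x@pa == 0L]
  switch(metric, auc = aucFromScores(p, b), tss = tssFromScores(p, b)$tss,
         stop("unsupported metric: ", metric))
}

.checkMetric <- function(metric) match.arg(metric, c("auc", "tss", "aicc"))

#' Evaluate a model configuration
#'
#' Computes the training value of a metric and, when a validation design
#' is supplied, the validation value: the metric on the hold-out table,
#' or for k-fold cross-validation the arithmetic mean of the per-fold
#' values (one model trained per fold).  AICc uses all observations and
#' accepts no partition.
#'
#' @param x training \linkS4class{SWD}.
#' @param method,hypers,seed model configuration (see
#'   \code{\link{trainSDM}}).
#' @param metric \code{"auc"}, \code{"tss"} or \code{"aicc"}.
#' @param val optional hold-out validation \linkS4class{SWD}.
#' @param folds optional \linkS4class{Folds} for cross-validation.
#' @param model optional pre-trained \linkS4class{TrainedSDM} (hold-out
#'   designs only; skips retraining).
#' @return list(metric, train, validation, perFold, higherIsBetter).
#' @export
evaluateModel <- function(x, method, hypers = list(), metric = "auc",
                          val = NULL, folds = NULL, seed = 1,
                          model = NULL) {
  metric <- .checkMetric(metric)
  if (metric == "aicc") {
    if (!is.null(folds) || !is.null(val))
      stop("AICc uses all observations; no validation partition applies")
    if (is.null(model)) model <- trainSDM(x, method, hypers, seed)
    return(list(metric = metric, train = aicc(model, x),
                validation = NA_real_, perFold = numeric(),
                higherIsBetter = FALSE))
  }
  if (!is.null(folds)) {
    perTrain <- perVal <- numeric(folds@k)
    for (i in seq_len(folds@k)) {
      tr <- swdSubset(x, records = which(folds@assignments != i))
      va <- swdSubset(x, records = which(folds@assignments == i))
      m <- trainSDM(tr, method, hypers, seed)
      perTrain[i] <- .scoreMetric(m, tr, metric)
      perVal[i] <- .scoreMetric(m, va, metric)
    }
    return(list(metric = metric, train = mean(perTrain),
                validation = mean(perVal), perFold = perVal,
                higherIsBetter = TRUE))
  }
  if (is.null(model)) model <- trainSDM(x, method, hypers, seed)
  list(metric = metric, train = .scoreMetric(model, x, metric),
       validation = if (is.null(val)) NA_real_
                    else .scoreMetric(model, val, metric),
       perFold = numeric(), higherIsBetter = TRUE)
}
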