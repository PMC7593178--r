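# Permutation importance and the leave-one-out variable jackknife used
# by both data-driven selection functions.

#' Permutation variable importance
#'
#' For each variable the column is shuffled (presences and contrasts
#' jointly) \code{nPermutations} times and the training metric is
#' recomputed; the raw importance is the mean metric drop, clamped at 0,
#' and raws are normalized to sum to 100 (when every drop is 0 the
#' importance is spread uniformly).
#'
#' @param model a \linkS4class{TrainedSDM}.
#' @param x evaluation \linkS4class{SWD} (defaults to the training
#'   table).
#' @param metric \code{"auc"} or \code{"tss"}.
#' @param nPermutations number of shuffles per variable (default 10).
#' @param seed integer seed.
#' @return data.frame(variable, importance) in percent, one row per
#'   model variable, summing to 100.
#' @export
permutationImportance <- function(model, x = model@swd, metric = "auc",
                                  nPermutations = 10, seed = 1) {
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  metric <- match.arg(metric, c("auc", "tss"))
  vars <- variableNames(model@swd)
  base <- .scoreMetric(model, x, metric)
  raw <- withSeed(seed, vapply(vars, function(v) {
    drops <- vapply(seq_len(nPermutations), function(i) {
      shuffled <- x
      shuffled@data[[v]] <- sample(shuffled@data[[v]])
      base - .scoreMetric(model, shuffled, metric)
    }, 0)
    max(0, mean(drops))
  }, 0))
  imp <- if (sum(raw) > 0) 100 * raw / sum(raw)
         else rep(100 / length(vars), length(vars))
  data.frame(variable = vars, importance = unname(imp))
}

#' Leave-one-out variable jackknife
#'
#' Retrains the model once per candidate variable with that variable
#' removed (same method, hyperparameters and seed) and reports the
#' chosen metric, either on the training data or on the validation
#' design.
#'
#' @param model a \linkS4class{TrainedSDM}.
#' @param x training \linkS4class{SWD}.
#' @param metric \code{"auc"} or \code{"tss"}.
#' @param candidates variable names to drop one at a time (must be
#'   model variables; empty gives an empty result).
#' @param scoreOn \code{"train"} or \code{"validation"}.
#' @param val,folds validation design (required for
#'   \code{scoreOn = "validation"}).
#' @return data.frame(variable, value): metric after retraining without
#'   each candidate.
#' @export
jackknifeDrop <- function(model, x = model@swd, metric = "auc",
                          candidates = variableNames(model@swd),
                          scoreOn = c("train", "validation"),
                          val = NULL, folds = NULL) {
  scoreOn <- match.arg(scoreOn)
  bad <- setdiff(candidates, variableNames(model@swd))
  if (length(bad))
    stop("candidate(s) not in the model: ", paste(bad, collapse = ", "))
  if (scoreOn == "validation" && is.null(val) && is.null(folds))
    stop("scoreOn = 'validation' requires val or folds")
  vals <- vapply(candidates, function(v) {
    keep <- setdiff(variableNames(x), v)
    ev <- evaluateModel(swdSubset(x, variables = keep), model@method,
                        model@hypers, metric,
                        val = if (is.null(val)) NULL
                              else swdSubset(val, variables = keep),
                        folds = folds, seed = model@seed)
    if (scoreOn == "train") ev$train else ev$validation
  }, 0)
  data.frame(variable = candidates, value = unname(vals),
             row.names = NULL)
}
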