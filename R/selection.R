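# Data-driven variable selection: collinearity removal (varSel) and
# parsimony reduction (reduceVar).  Both remove exactly one variable per
# step, log every step, and never produce a model with zero predictors.

#' Pairwise rank correlation of the covariates
#'
#' Spearman (default) or Pearson correlation over the contrast records,
#' optionally on a seeded subsample.
#'
#' @param x an \linkS4class{SWD}.
#' @param method \code{"spearman"} or \code{"pearson"}.
#' @param sample optional number of contrast records to subsample; more
#'   than available uses all (with a warning).
#' @param seed integer seed for the subsample.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
swdCor <- function(x, method = c("spearman", "pearson"), sample = NULL,
                   seed = 1) {
  method <- match.arg(method)
  if (ncol(x@data) < 2L) stop("need at least two variables")
  idx <- which(x@pa == 0L)
  if (!is.null(sample)) {
    if (sample > length(idx)) {
      warning("sample exceeds available contrast records; using all")
    } else {
      idx <- withSeed(seed, sort(base::sample(idx, sample)))
    }
  }
  stats::cor(x@data[idx, , drop = FALSE], method = method,
             use = "pairwise.complete.obs")
}

.maxOffDiag <- function(cm) {
  diag(cm) <- 0
  max(abs(cm))
}

.emptyTrace <- function() {
  data.frame(step = integer(), removed = character(),
             reason = character(), metricBefore = numeric(),
             metricAfter = numeric(), stringsAsFactors = FALSE)
}

#' Remove highly correlated variables (data-driven)
#'
#' Iterates until all pairwise correlations among the retained variables
#' fall below \code{corThreshold}: rank variables by permutation
#' importance; take the most important variable correlated (|rho| >=
#' threshold) with any other; form its correlated group (the focal
#' variable plus every variable meeting the threshold against it); run a
#' leave-one-out jackknife on the group scored on the \emph{training}
#' data; discard the group member whose removal decreases the training
#' metric least; retrain.  Ties break toward the variable with lower
#' permutation importance, then lexicographic name order.  Exactly one
#' variable is removed per step.
#'
#' @param x training \linkS4class{SWD}.
#' @param method,hypers,seed model configuration.
#' @param metric \code{"auc"} or \code{"tss"}.
#' @param corThreshold correlation threshold in (0, 1].
#' @param corMethod \code{"spearman"} (default) or \code{"pearson"}.
#' @param sample optional background subsample size for the correlation
#'   matrix.
#' @param nPermutations permutations for the importance ranking.
#' @param protectFocal if TRUE the focal (most important) variable is
#'   never the one removed from its group; by default it competes like
#'   any other group member and the jackknife arbitrates.
#' @return list(model = final \linkS4class{TrainedSDM},
#'   trace = data.frame(step, removed, reason, metricBefore,
#'   metricAfter), retained = character()).
#' @export
varSel <- function(x, method, hypers = list(), metric = "auc",
                   corThreshold = 0.7, corMethod = "spearman",
                   sample = NULL, nPermutations = 10,
                   protectFocal = FALSE, seed = 1) {
  if (corThreshold <= 0 || corThreshold > 1)
    stop("corThreshold must be in (0, 1]")
  metric <- match.arg(metric, c("auc", "tss"))
  cmFull <- swdCor(x, corMethod, sample, seed)
  cur <- x
  model <- trainSDM(cur, method, hypers, seed)
  trace <- .emptyTrace()
  step <- 0L
  repeat {
    vars <- variableNames(cur)
    if (length(vars) < 2L) break
    cm <- cmFull[vars, vars]
    if (.maxOffDiag(cm) < corThreshold) break
    step <- step + 1L
    imp <- permutationImportance(model, cur, metric, nPermutations, seed)
    imp <- imp[order(-imp$importance, imp$variable), ]
    focal <- NULL
    for (v in imp$variable) {
      others <- setdiff(vars, v)
      if (any(abs(cm[v, others]) >= corThreshold)) { focal <- v; break }
    }
    group <- c(focal,
               setdiff(vars, focal)[abs(cm[focal, setdiff(vars, focal)]) >=
                                      corThreshold])
    candidates <- if (protectFocal) setdiff(group, focal) else group
    before <- .scoreMetric(model, cur, metric)
    jk <- jackknifeDrop(model, cur, metric, candidates, scoreOn = "train")
    jk$importance <- imp$importance[match(jk$variable, imp$variable)]
    # highest remaining metric = least performance decrease; ties break
    # toward lower importance, then name order
    jk <- jk[order(-jk$value, jk$importance, jk$variable), ]
    drop <- jk$variable[1L]
    cur <- swdSubset(cur, variables = setdiff(vars, drop))
    model <- trainSDM(cur, method, hypers, seed)
    after <- .scoreMetric(model, cur, metric)
    logStep("varSel", "step ", step, ": removed ", drop,
            " (collinear); train ", metric, " ",
            sprintf("%.4f -> %.4f", before, after))
    trace <- rbind(trace, data.frame(step = step, removed = drop,
                                     reason = "collinear",
                                     metricBefore = before,
                                     metricAfter = after))
  }
  stopifnot(length(variableNames(cur)) < 2L ||
              .maxOffDiag(cmFull[variableNames(cur), variableNames(cur)]) <
                corThreshold)
  list(model = model, trace = trace, retained = variableNames(cur))
}

#' Remove low-importance variables (parsimony)
#'
#' Without the jackknife: repeatedly remove the lowest-importance
#' variable while its importance is below \code{threshold}, retraining
#' and re-ranking after each removal (at least one variable always
#' remains).  With the jackknife: among the variables below the
#' threshold, starting from the lowest-ranked, a variable is removed
#' only if the \emph{validation} metric after retraining is at least the
#' current model's validation metric; the process repeats until every
#' sub-threshold variable is either removed or proven necessary.
#'
#' @param x training \linkS4class{SWD}.
#' @param method,hypers,seed model configuration.
#' @param metric \code{"auc"} or \code{"tss"}.
#' @param threshold importance threshold in percent, [0, 100].
#' @param useJackknife logical; the jackknife variant requires a
#'   validation design (\code{val} or \code{folds}).
#' @param val,folds validation design.
#' @param nPermutations permutations for the importance ranking.
#' @return list(model, trace, retained) as in \code{\link{varSel}};
#'   trace metrics are validation values for the jackknife variant,
#'   training values otherwise.
#' @export
reduceVar <- function(x, method, hypers = list(), metric = "auc",
                      threshold = 2, useJackknife = TRUE, val = NULL,
                      folds = NULL, nPermutations = 10, seed = 1) {
  if (threshold < 0 || threshold > 100)
    stop("threshold must be in [0, 100] percent")
  metric <- match.arg(metric, c("auc", "tss"))
  if (useJackknife && is.null(val) && is.null(folds))
    stop("the jackknife variant requires a validation design (val or folds)")
  cur <- x
  model <- trainSDM(cur, method, hypers, seed)
  score <- function(swdTrain, mdl) {
    ev <- evaluateModel(swdTrain, method, hypers, metric,
                        val = if (is.null(val)) NULL else
                          swdSubset(val, variables = variableNames(swdTrain)),
                        folds = folds, seed = seed, model = mdl)
    if (useJackknife) ev$validation else ev$train
  }
  trace <- .emptyTrace()
  step <- 0L
  proven <- character()
  repeat {
    vars <- variableNames(cur)
    if (length(vars) < 2L) break
    imp <- permutationImportance(model, cur, metric, nPermutations, seed)
    low <- imp[imp$importance < threshold &
                 !(imp$variable %in% proven), , drop = FALSE]
    if (!nrow(low)) break
    low <- low[order(low$importance, low$variable), ]
    cand <- low$variable[1L]
    before <- score(cur, model)
    keep <- setdiff(vars, cand)
    newSwd <- swdSubset(cur, variables = keep)
    newModel <- trainSDM(newSwd, method, hypers, seed)
    after <- score(newSwd, if (is.null(folds)) newModel else NULL)
    if (useJackknife && after < before) {
      proven <- c(proven, cand)
      logStep("reduceVar", "kept ", cand, " (removal lowers validation ",
              metric, " ", sprintf("%.4f -> %.4f", before, after), ")")
      next
    }
    step <- step + 1L
    cur <- newSwd
    model <- newModel
    logStep("reduceVar", "step ", step, ": removed ", cand,
            " (low importance); ", metric, " ",
            sprintf("%.4f -> %.4f", before, after))
    trace <- rbind(trace, data.frame(step = step, removed = cand,
                                     reason = "low_importance",
                                     metricBefore = before,
                                     metricAfter = after))
  }
  list(model = model, trace = trace, retained = variableNames(cur))
}

#' Serialize a selection trace
#'
#' @param trace the trace data.frame from \code{\link{varSel}} or
#'   \code{\link{reduceVar}}.
#' @param path CSV output path.
#' @export
writeTrace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
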