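# Uniform train/predict contract over the four model families.
#
# ANN delegates to nnet, RF to randomForest, BRT to xgboost (gradient
# boosted trees with the classical BRT hyperparameter surface), and the
# Maxent-style method (ME) is fitted natively: l/q/p/h feature expansion
# plus an L1-penalized presence-vs-background binomial likelihood solved
# by glmnet, so no Java runtime is involved anywhere.

.METHODS <- c("ANN", "BRT", "RF", "ME")

# Hyperparameter schema per method with the canonical defaults: ME
# feature classes lqph / regularization multiplier 1 / 500 iterations;
# RF 500 trees, mtry floor(sqrt(#variables)), node size 1; BRT 100
# trees, depth 1, shrinkage 0.1, bag fraction 0.5; ANN decay 0, initial
# weight range 0.7, 100 iterations (hidden-layer size has no default
# and resolves to the number of variables when unset).
.SCHEMAS <- list(
  ANN = list(size = NA, decay = 0, rang = 0.7, maxit = 100),
  BRT = list(n_trees = 100, interaction_depth = 1, shrinkage = 0.1,
             bag_fraction = 0.5),
  RF = list(n_trees = 500, mtry = NA, nodesize = 1),
  ME = list(fc = "lqph", reg = 1, iter = 500)
)

# background cap for the Maxent-style method: tables with more contrast
# records are downsampled (seeded) to this many before fitting
.ME_BG_CAP <- 10000L

#' Hyperparameter schema and defaults
#'
#' @param method one of ANN, BRT, RF, ME.
#' @return named list of hyperparameters with their default values
#'   (\code{NA} = no default: ANN hidden-layer size resolves to the
#'   number of variables, RF \code{mtry} to
#'   \code{floor(sqrt(n_variables))} at training time).
#' @export
hyperSchema <- function(method) {
  method <- match.arg(method, .METHODS)
  .SCHEMAS[[method]]
}

#' @rdname hyperSchema
#' @param hypers named list of user-supplied hyperparameter values;
#'   names outside the method's schema are an error.
#' @param nVariables number of variables, used to resolve data-dependent
#'   defaults.
#' @return \code{defaultHypers}: complete, resolved hyperparameter list.
#' @export
defaultHypers <- function(method, hypers = list(), nVariables = NULL) {
  schema <- hyperSchema(method)
  bad <- setdiff(names(hypers), names(schema))
  if (length(bad))
    stop("unknown hyperparameter(s) for ", method, ": ",
         paste(bad, collapse = ", "))
  out <- utils::modifyList(schema, hypers)
  if (!is.null(nVariables)) {
    if (method == "RF" && is.na(out$mtry))
      out$mtry <- max(1L, floor(sqrt(nVariables)))
    if (method == "ANN" && is.na(out$size)) out$size <- nVariables
  }
  out
}

#' Default background cap of the Maxent-style method
#' @return integer cap (10000).
#' @export
meBackgroundCap <- function() .ME_BG_CAP

# collect warnings raised in expr into a character vector `notes`
# (non-convergence is recorded, never thrown, so tuning loops that probe
# low iteration counts keep running)
.collectNotes <- function(expr) {
  notes <- character()
  val <- withCallingHandlers(expr, warning = function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, notes = notes)
}

#' Train a species distribution model
#'
#' @param x training \linkS4class{SWD}; the Maxent-style method requires
#'   a background-contrast table and caps the background at
#'   \code{meBackgroundCap()} records (seeded downsampling).
#' @param method one of \code{"ANN"}, \code{"BRT"}, \code{"RF"},
#'   \code{"ME"}.
#' @param hypers named list of hyperparameter values; unset ones take
#'   the schema defaults (see \code{\link{hyperSchema}}).
#' @param seed integer seed; training is deterministic given
#'   (x, method, hypers, seed).
#' @return a \linkS4class{TrainedSDM}.  Convergence warnings from the
#'   backend are recorded in the \code{notes} slot, not thrown.
#' @export
trainSDM <- function(x, method, hypers = list(), seed = 1) {
  method <- match.arg(method, .METHODS)
  validObject(x)
  if (nPresence(x) < 1L || nContrast(x) < 1L)
    stop("training requires at least one presence and one contrast record")
  if (method == "ME" && x@contrastKind != "background")
    stop("the Maxent-style method requires background contrast records, ",
         "not absences")
  hp <- defaultHypers(method, hypers, nVariables = ncol(x@data))
  seed <- as.integer(seed)
  if (method == "ME" && nContrast(x) > .ME_BG_CAP) {
    keepBg <- withSeed(seed, sample(which(x@pa == 0L), .ME_BG_CAP))
    x <- swdSubset(x, records = sort(c(which(x@pa == 1L), keepBg)))
  }
  fitted <- withSeed(seed, .collectNotes(switch(method,
    ME = .fitME(x, hp),
    ANN = .fitANN(x, hp),
    BRT = .fitBRT(x, hp, seed),
    RF = .fitRF(x, hp))))
  st <- fitted$value
  new("TrainedSDM", method = method, hypers = hp, seed = seed,
      fit = st$fit, swd = x,
      featureMap = if (is.null(st$map)) data.frame() else st$map,
      ranges = if (is.null(st$ranges)) data.frame() else st$ranges,
      coefs = if (is.null(st$coefs)) numeric() else st$coefs,
      Z = if (is.null(st$Z)) NA_real_ else st$Z,
      entropy = if (is.null(st$H)) NA_real_ else st$H,
      notes = fitted$notes)
}

.fitANN <- function(x, hp) {
  df <- data.frame(.pa = x@pa, x@data)
  fit <- nnet::nnet(stats::as.formula(".pa ~ ."), data = df,
                    size = hp$size, decay = hp$decay, rang = hp$rang,
                    maxit = hp$maxit, entropy = TRUE, trace = FALSE)
  list(fit = fit)
}

.fitRF <- function(x, hp) {
  fit <- randomForest::randomForest(
    x = x@data, y = factor(x@pa, levels = c(0L, 1L)),
    ntree = hp$n_trees, mtry = min(hp$mtry, ncol(x@data)),
    nodesize = hp$nodesize)
  list(fit = fit)
}

.fitBRT <- function(x, hp, seed) {
  dm <- xgboost::xgb.DMatrix(as.matrix(x@data), label = x@pa)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = hp$interaction_depth, eta = hp$shrinkage,
                  subsample = hp$bag_fraction, nthread = 1, seed = seed),
    data = dm, nrounds = hp$n_trees, verbose = 0)
  list(fit = fit)
}

# Maxent-style fit: expanded features, presence weight 1 / background
# weight 100 (the standard infinitely-weighted logistic approximation),
# per-feature L1 penalty lambda_j = reg * sd_j(presences) / sqrt(nP)
# for l/q/p features and reg * 0.5 / sqrt(nP) for hinge features (a
# constant per-variable hinge budget).  glmnet solves the penalized
# binomial likelihood along a descending lambda path whose final value
# scales the mean penalty by nP / sum(weights).
.fitME <- function(x, hp) {
  ex <- expandFeatures(x, classes = hp$fc)
  X <- ex$matrix
  y <- x@pa
  np <- sum(y == 1L)
  sdP <- apply(X[y == 1L, , drop = FALSE], 2L, stats::sd)
  isHinge <- ex$map$kind %in% c("hinge_fwd", "hinge_rev")
  pen <- ifelse(isHinge, 0.5, pmax(sdP, 0.05)) * hp$reg / sqrt(np)
  w <- ifelse(y == 1L, 1, 100)
  Xfit <- X
  if (ncol(Xfit) == 1L) Xfit <- cbind(Xfit, .dummy_ = 0)
  lamTop <- mean(pen) * np / sum(w)
  path <- 10^seq(4, 0, length.out = 200) * lamTop
  fit <- glmnet::glmnet(Xfit, y, family = "binomial", weights = w,
                        lambda = path,
                        penalty.factor = c(pen, rep(1, ncol(Xfit) - length(pen))),
                        standardize = FALSE, maxit = hp$iter)
  nsol <- length(fit$lambda)
  if (nsol < length(path))
    warning("Maxent-style fit did not converge within ", hp$iter,
            " iterations; using the last converged solution")
  beta <- as.numeric(fit$beta[seq_len(ncol(X)), nsol])
  b0 <- fit$a0[nsol]
  coefs <- c(`(intercept)` = unname(b0),
             stats::setNames(beta, colnames(X)))
  etaBg <- b0 + as.numeric(X[y == 0L, , drop = FALSE] %*% beta)
  Z <- sum(exp(etaBg))
  raw <- exp(etaBg) / Z
  H <- -sum(ifelse(raw > 0, raw * log(raw), 0))
  list(fit = fit, map = ex$map, ranges = attr(ex$map, "ranges"),
       coefs = coefs, Z = Z, H = H)
}

.meEta <- function(object, df) {
  X <- applyFeatureMap(object@featureMap, object@ranges, df)
  object@coefs[1L] + as.numeric(X %*% object@coefs[-1L])
}

#' Predict at point locations
#'
#' @param object a \linkS4class{TrainedSDM}.
#' @param newdata an \linkS4class{SWD}, data.frame of covariates, or
#'   \linkS4class{GridStack} (see \code{\link{predictRaster}}).
#' @param type output scale.  For the Maxent-style method:
#'   \code{"raw"} = exp(eta)/Z (sums to 1 over the training background),
#'   \code{"cloglog"} = 1 - exp(-exp(H) * raw) (the default),
#'   \code{"logistic"} = exp(H)*raw / (1 + exp(H)*raw).  For
#'   ANN/BRT/RF the default is the positive-class probability and the
#'   Maxent-specific scales are an error.  Covariates outside the
#'   Maxent-style training range are clamped before feature evaluation.
#' @param ... unused.
#' @return numeric vector, one score per record; rows with a missing
#'   covariate give NA.
#' @export
setMethod("predict", "TrainedSDM", function(object, newdata,
                                            type = "default", ...) {
  if (is(newdata, "GridStack"))
    return(predictRaster(object, newdata, type = type))
  df <- if (is(newdata, "SWD")) newdata@data else as.data.frame(newdata)
  miss <- setdiff(variableNames(object@swd), colnames(df))
  if (length(miss))
    stop("missing variable(s): ", paste(miss, collapse = ", "))
  df <- df[, variableNames(object@swd), drop = FALSE]
  ok <- stats::complete.cases(df)
  out <- rep(NA_real_, nrow(df))
  if (!any(ok)) return(out)
  dfc <- df[ok, , drop = FALSE]
  type <- match.arg(type, c("default", "raw", "cloglog", "logistic"))
  if (object@method == "ME") {
    eta <- .meEta(object, dfc)
    raw <- exp(eta) / object@Z
    eH <- exp(object@entropy)
    out[ok] <- switch(type,
      raw = raw,
      default = ,
      cloglog = 1 - exp(-eH * raw),
      logistic = eH * raw / (1 + eH * raw))
  } else {
    if (type %in% c("raw", "cloglog"))
      stop("output type '", type, "' is specific to the Maxent-style method")
    out[ok] <- switch(object@method,
      ANN = as.numeric(predict(object@fit, dfc, type = "raw")),
      RF = predict(object@fit, dfc, type = "prob")[, "1"],
      BRT = as.numeric(predict(object@fit,
                               xgboost::xgb.DMatrix(as.matrix(dfc)))))
  }
  out
})

#' Save / load a trained model
#'
#' The archive stores the method, hyperparameters, seed, feature map,
#' coefficients, training ranges and training data — everything needed
#' to reproduce predictions bit-for-bit.
#'
#' @param model a \linkS4class{TrainedSDM}.
#' @param path file path (.rds archive).
#' @return \code{loadSDM}: the restored \linkS4class{TrainedSDM}.
#' @export
saveSDM <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveSDM
#' @export
loadSDM <- function(path) readRDS(path)
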