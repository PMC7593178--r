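# Raster prediction, binary maps, response curves and the model report.

#' Project a model over a raster stack
#'
#' Cellwise identical to point prediction on each cell's covariate
#' vector.  Cells with any missing covariate are missing in the output;
#' \code{normalize = TRUE} with \code{type = "raw"} renormalizes the
#' Maxent-style raw output to sum 1 over the full extent (as required
#' for AICc over a study area).
#'
#' @param model a \linkS4class{TrainedSDM}.
#' @param stack a \linkS4class{GridStack} whose layers cover all model
#'   variables.
#' @param type output scale, as in \code{\link{predict,TrainedSDM-method}}.
#' @param normalize renormalize raw output over the extent.
#' @return a numeric matrix aligned to the stack, with the output kind
#'   in attribute \code{"output"}.
#' @export
predictRaster <- function(model, stack, type = "default",
                          normalize = FALSE) {
  vars <- variableNames(model@swd)
  miss <- setdiff(vars, names(stack@layers))
  if (length(miss))
    stop("stack misses layer(s): ", paste(miss, collapse = ", "))
  d <- dim(stack@layers[[1L]])
  df <- as.data.frame(lapply(stack@layers[vars], as.vector))
  sc <- predict(model, df, type = type)
  if (normalize) {
    if (type != "raw")
      stop("normalize applies to the raw output only")
    sc <- sc / sum(sc[is.finite(sc)])
  }
  out <- matrix(sc, d[1L], d[2L])
  attr(out, "output") <- type
  out
}

#' Threshold a prediction raster into a binary map
#'
#' @param raster numeric matrix (e.g. from \code{\link{predictRaster}}).
#' @param threshold finite threshold; cells >= threshold become 1, other
#'   finite cells 0, missing cells stay missing.
#' @return an integer 0/1 matrix with NAs preserved.
#' @export
binarize <- function(raster, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  out <- ifelse(is.na(raster), NA_integer_,
                as.integer(raster >= threshold))
  matrix(out, nrow(raster), ncol(raster))
}

#' Marginal response curve of one variable
#'
#' Evaluates the model over \code{nPoints} values spanning the
#' variable's training range while every other variable is held at its
#' training mean.
#'
#' @param model a \linkS4class{TrainedSDM}.
#' @param variable variable name.
#' @param nPoints number of evaluation points (default 100).
#' @param type output scale.
#' @return data.frame(value, prediction).
#' @export
responseCurve <- function(model, variable, nPoints = 100,
                          type = "default") {
  vars <- variableNames(model@swd)
  if (!variable %in% vars) stop("unknown variable: ", variable)
  dat <- model@swd@data
  grid <- seq(min(dat[[variable]], na.rm = TRUE),
              max(dat[[variable]], na.rm = TRUE), length.out = nPoints)
  df <- as.data.frame(lapply(dat, function(col)
    rep(mean(col, na.rm = TRUE), nPoints)))
  df[[variable]] <- grid
  data.frame(value = grid, prediction = predict(model, df, type = type))
}

# ROC curve points (FPR, TPR) over all observed thresholds
.rocData <- function(presence, contrast) {
  cand <- c(Inf, sort(unique(c(presence, contrast)), decreasing = TRUE))
  data.frame(
    fpr = vapply(cand, function(t) mean(contrast >= t), 0),
    tpr = vapply(cand, function(t) mean(presence >= t), 0))
}

.tryPlot <- function(path, expr) {
  ok <- tryCatch({
    grDevices::png(path, width = 640, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr
    TRUE
  }, error = function(e) FALSE)
  invisible(ok)
}

#' Create a model report
#'
#' Writes a self-contained bundle into \code{dir}: a markdown and an
#' HTML document with the hyperparameters, train/validation/test metric
#' values, the permutation-importance table, response-curve and ROC
#' figures and the threshold table, plus machine-readable sidecars
#' (\code{metrics.json}, \code{importance.csv}, \code{thresholds.csv},
#' and the selection/tuning traces when supplied).  Regeneration with
#' the same inputs and seed reproduces the sidecar CSVs byte for byte.
#'
#' @param model a \linkS4class{TrainedSDM}.
#' @param dir output directory (created if needed).
#' @param val,test optional validation / held-out test
#'   \linkS4class{SWD} tables.
#' @param metric \code{"auc"} or \code{"tss"}.
#' @param trace optional selection trace data.frame.
#' @param tune optional \linkS4class{TuneResult}.
#' @param nPermutations,seed importance settings.
#' @return invisibly, the path of the markdown report.
#' @export
modelReport <- function(model, dir, val = NULL, test = NULL,
                        metric = "auc", trace = NULL, tune = NULL,
                        nPermutations = 10, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vars <- variableNames(model@swd)
  scTrain <- predict(model, model@swd)
  p <- scTrain[model@swd@pa == 1L]; b <- scTrain[model@swd@pa == 0L]

  metrics <- list(metric = metric,
                  train = .scoreMetric(model, model@swd, metric))
  if (!is.null(val)) metrics$validation <- .scoreMetric(model, val, metric)
  if (!is.null(test)) metrics$test <- .scoreMetric(model, test, metric)
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  imp <- permutationImportance(model, model@swd, metric = "auc",
                               nPermutations = nPermutations, seed = seed)
  utils::write.csv(imp, file.path(dir, "importance.csv"),
                   row.names = FALSE)

  thr <- data.frame(
    rule = c("max_tss", "equal_sens_spec", "min_training_presence"),
    threshold = c(selectThreshold(p, b, "max_tss"),
                  selectThreshold(p, b, "equal_sens_spec"),
                  selectThreshold(p, b, "min_training_presence")))
  utils::write.csv(thr, file.path(dir, "thresholds.csv"),
                   row.names = FALSE)

  if (!is.null(trace)) writeTrace(trace, file.path(dir, "trace.csv"))
  if (!is.null(tune))
    writeTuneResult(tune, file.path(dir, "tuning.csv"),
                    file.path(dir, "tuning.json"))

  roc <- .rocData(p, b)
  .tryPlot(file.path(dir, "roc.png"), {
    graphics::plot(roc$fpr, roc$tpr, type = "l", xlab = "1 - specificity",
                   ylab = "sensitivity", main = "ROC (training data)")
    graphics::abline(0, 1, lty = 2)
  })
  for (v in vars) {
    rc <- responseCurve(model, v)
    .tryPlot(file.path(dir, paste0("response_", v, ".png")),
             graphics::plot(rc$value, rc$prediction, type = "l",
                            xlab = v, ylab = "prediction",
                            main = paste("Response of", v)))
  }

  hp <- vapply(model@hypers, function(x) paste(x, collapse = ""), "")
  md <- c(
    paste("#", speciesName(model@swd), "—", model@method, "model report"),
    "", "## Hyperparameters", "",
    paste0("- ", names(hp), ": ", hp),
    "", "## Performance", "",
    paste0("- training ", metric, ": ",
           sprintf("%.4f", metrics$train)),
    if (!is.null(val)) paste0("- validation ", metric, ": ",
                              sprintf("%.4f", metrics$validation)),
    if (!is.null(test)) paste0("- test ", metric, ": ",
                               sprintf("%.4f", metrics$test)),
    "", "## Variable importance (permutation)", "",
    "| variable | importance (%) |", "|---|---|",
    sprintf("| %s | %.2f |", imp$variable, imp$importance),
    "", "## Thresholds", "",
    "| rule | threshold |", "|---|---|",
    sprintf("| %s | %.6f |", thr$rule, thr$threshold),
    "", "## Figures", "",
    "![ROC](roc.png)", "",
    sprintf("![response %s](response_%s.png)", vars, vars))
  if (!is.null(trace) && nrow(trace)) {
    md <- c(md, "", "## Variable selection trace", "",
            "| step | removed | reason | before | after |",
            "|---|---|---|---|---|",
            sprintf("| %d | %s | %s | %.4f | %.4f |", trace$step,
                    trace$removed, trace$reason, trace$metricBefore,
                    trace$metricAfter))
  }
  if (!is.null(tune)) {
    md <- c(md, "", "## Hyperparameter tuning", "",
            paste0("- trainings: ", tune@trainings,
                   " (cache hits: ", tune@cacheHits, ")"),
            paste0("- best combination: ",
                   .comboKey(tune@combos[[1L]])))
  }
  mdPath <- file.path(dir, "report.md")
  writeLines(md, mdPath)
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>Model report</title></head><body><pre>",
            vapply(md, function(l)
              gsub("<", "&lt;", gsub("&", "&amp;", l)), ""),
            "</pre></body></html>")
  writeLines(html, file.path(dir, "report.html"))
  invisible(mdPath)
}
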