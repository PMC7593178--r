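#' @import methods
#' @importFrom stats predict quantile sd cor runif rnorm plogis setNames
#' @importFrom utils read.csv write.csv head count.fields
NULL

#' SWD: samples with data
#'
#' The universal data container of the package: one row per record
#' (presence or contrast location) holding the species label, the X/Y
#' coordinates, the binary presence flag and the environmental covariate
#' values at that location.  Contrast records are either random
#' \emph{background} locations (presence-only designs) or confirmed
#' \emph{absences}.
#'
#' Coordinates are metadata only: they are carried through I/O and fold
#' import but never used by any model.
#'
#' @slot species single character label.
#' @slot coords data.frame with numeric columns \code{X}, \code{Y}.
#' @slot pa integer vector, 1 = presence, 0 = contrast.
#' @slot data data.frame of environmental covariates (one column per
#'   variable, no duplicated names).
#' @slot contrastKind \code{"background"} or \code{"absence"}.
#'
#' @aliases SWD-class
#' @exportClass SWD
setClass("SWD",
  slots = c(
    species = "character",
    coords = "data.frame",
    pa = "integer",
    data = "data.frame",
    contrastKind = "character"
  )
)

setValidity("SWD", function(object) {
  n <- length(object@pa)
  if (nrow(object@coords) != n || nrow(object@data) != n)
    return("coords, pa and data must describe the same number of records")
  if (!all(c("X", "Y") %in% colnames(object@coords)))
    return("coords must have columns X and Y")
  if (!all(object@pa %in% c(0L, 1L)))
    return("pa must be 0 (contrast) or 1 (presence)")
  if (ncol(object@data) < 1L)
    return("at least one environmental variable is required")
  if (anyDuplicated(colnames(object@data)))
    return("duplicated variable names")
  if (length(object@contrastKind) != 1L ||
      !object@contrastKind %in% c("background", "absence"))
    return("contrastKind must be 'background' or 'absence'")
  TRUE
})

#' Construct an SWD object
#'
#' @param species species label (single string).
#' @param coords data.frame (or matrix) with columns \code{X}, \code{Y}.
#' @param pa binary vector: 1 presence, 0 contrast.
#' @param data data.frame of covariate values, one row per record.
#' @param contrastKind \code{"background"} or \code{"absence"}.
#' @return an \linkS4class{SWD} object.
#' @export
SWD <- function(species, coords, pa, data, contrastKind = "background") {
  coords <- as.data.frame(coords)
  colnames(coords) <- c("X", "Y")
  new("SWD", species = as.character(species)[1L], coords = coords,
      pa = as.integer(pa), data = as.data.frame(data),
      contrastKind = contrastKind)
}

#' Fold assignment for cross-validation
#'
#' Maps every record of an \linkS4class{SWD} to one of k folds.  Folds are
#' created randomly with \code{\link{randomFolds}} (class-stratified) or
#' wrapped from externally constructed (e.g. spatial-block) ids with
#' \code{\link{importFolds}}.
#'
#' @slot kind \code{"random"} or \code{"imported"}.
#' @slot assignments integer fold id per record, in \code{1..k}.
#' @slot k number of folds.
#' @slot seed seed used to create random folds (NA for imported).
#'
#' @aliases Folds-class
#' @exportClass Folds
setClass("Folds",
  slots = c(kind = "character", assignments = "integer",
            k = "integer", seed = "integer")
)

setValidity("Folds", function(object) {
  if (object@k < 2L) return("k must be >= 2")
  if (!all(object@assignments %in% seq_len(object@k)))
    return("fold ids must lie in 1..k")
  TRUE
})

#' Raster stack on a regular grid
#'
#' A lightweight stack of aligned single-band grids: a named list of
#' equally sized numeric matrices with a unit-cell geotransform (cell
#' (r, c) has centre X = c - 0.5, Y = nrow - r + 0.5, row 1 at the top).
#' NA cells mark missing data.
#'
#' @slot layers named list of numeric matrices of identical dimension.
#' @aliases GridStack-class
#' @exportClass GridStack
setClass("GridStack", slots = c(layers = "list"))

setValidity("GridStack", function(object) {
  if (length(object@layers) < 1L) return("at least one layer is required")
  if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
    return("layers must have unique names")
  d <- dim(object@layers[[1L]])
  ok <- vapply(object@layers, function(m)
    is.matrix(m) && is.numeric(m) && identical(dim(m), d), logical(1))
  if (!all(ok)) return("all layers must be numeric matrices of equal dimension")
  TRUE
})

#' Construct a GridStack
#' @param layers named list of numeric matrices of identical dimension.
#' @return a \linkS4class{GridStack}.
#' @export
gridStack <- function(layers) new("GridStack", layers = layers)

#' Virtual species configuration
#'
#' Describes a simulated landscape and species with known truth: smooth
#' standardized environmental layers (optionally with noisy duplicates),
#' a logistic suitability surface over a linear combination of layers,
#' and presence / absence / background sample sizes.
#'
#' @slot rows,cols grid dimension.
#' @slot nLayers number of layers.
#' @slot coefs numeric vector of length nLayers: suitability coefficient
#'   per layer (0 = uninformative).
#' @slot intercept suitability intercept.
#' @slot duplicates data.frame(layer, source, sd): layer \code{layer} is
#'   replaced by layer \code{source} plus Gaussian noise of sd \code{sd}.
#' @slot noiseLayers integer indices of layers generated as unsmoothed
#'   (spatially independent) white noise — covariates carrying no
#'   structure at all.
#' @slot smoothness spatial autocorrelation length of the random fields,
#'   in cells.
#' @slot nPresence,nAbsence,nBackground sample sizes.
#' @slot seed integer seed.
#'
#' @aliases VirtualSpeciesConfig-class
#' @exportClass VirtualSpeciesConfig
setClass("VirtualSpeciesConfig",
  slots = c(rows = "integer", cols = "integer", nLayers = "integer",
            coefs = "numeric", intercept = "numeric",
            duplicates = "data.frame", noiseLayers = "integer",
            smoothness = "numeric",
            nPresence = "integer", nAbsence = "integer",
            nBackground = "integer", seed = "integer")
)

setValidity("VirtualSpeciesConfig", function(object) {
  if (object@rows < 1L || object@cols < 1L) return("grid shape must be positive")
  if (length(object@coefs) != object@nLayers)
    return("coefs must have one value per layer")
  if (nrow(object@duplicates)) {
    if (!all(c("layer", "source", "sd") %in% colnames(object@duplicates)))
      return("duplicates needs columns layer, source, sd")
    if (any(object@duplicates$layer > object@nLayers) ||
        any(object@duplicates$source > object@nLayers))
      return("duplicate indices must reference existing layers")
    if (any(object@duplicates$layer == object@duplicates$source))
      return("a layer cannot duplicate itself")
    if (any(object@duplicates$sd < 0)) return("duplicate noise sd must be >= 0")
  }
  if (length(object@noiseLayers) &&
      any(object@noiseLayers < 1L | object@noiseLayers > object@nLayers))
    return("noiseLayers must reference existing layers")
  ncell <- object@rows * object@cols
  if (max(object@nPresence, object@nAbsence, object@nBackground) > ncell)
    return("requested sample counts exceed the number of cells")
  if (object@smoothness <= 0) return("smoothness must be positive")
  TRUE
})

#' A fitted species distribution model
#'
#' Bundles the fitted backend with everything needed to reproduce its
#' predictions: method, hyperparameters, training data, and for the
#' Maxent-style method the feature map, per-variable training ranges,
#' background normalizer Z and the entropy H of the raw distribution.
#'
#' @slot method one of \code{"ANN"}, \code{"BRT"}, \code{"RF"}, \code{"ME"}.
#' @slot hypers named list of resolved hyperparameter values.
#' @slot seed integer seed used for training.
#' @slot fit opaque fitted backend object.
#' @slot swd training \linkS4class{SWD}.
#' @slot featureMap data.frame describing expanded features (ME only).
#' @slot ranges data.frame(variable, min, max) of training covariate
#'   ranges, used for clamping (ME only).
#' @slot coefs named numeric vector of fitted feature coefficients
#'   including the intercept (ME only).
#' @slot Z normalizer: sum of exp(eta) over training background (ME only).
#' @slot entropy entropy H of the raw distribution over training
#'   background (ME only).
#' @slot notes character vector of recorded training warnings
#'   (e.g. non-convergence); never an exception.
#'
#' @aliases TrainedSDM-class
#' @exportClass TrainedSDM
setClass("TrainedSDM",
  slots = c(method = "character", hypers = "list", seed = "integer",
            fit = "ANY", swd = "SWD", featureMap = "data.frame",
            ranges = "data.frame", coefs = "numeric", Z = "numeric",
            entropy = "numeric", notes = "character")
)

#' Hyperparameter grid
#'
#' Named candidate-value domains for one method.  The Cartesian product
#' of the domains is the tuning search space.
#'
#' @slot method model method.
#' @slot domains named list: hyperparameter name -> vector of candidate
#'   values.
#' @aliases HyperGrid-class
#' @exportClass HyperGrid
setClass("HyperGrid", slots = c(method = "character", domains = "list"))

#' Result of a tuning run
#'
#' @slot method,metric method and evaluation metric used.
#' @slot results data.frame, one row per evaluated hyperparameter
#'   combination with train/validation scores, ranked best first
#'   (\code{rankFitness} order; row 1 is the best combination).
#' @slot combos list of hyperparameter lists, aligned with
#'   \code{results} rows.
#' @slot trainings number of model-training requests issued.
#' @slot cacheHits number of requests served from the evaluation cache
#'   (duplicated offspring); fits performed = trainings - cacheHits.
#' @slot generations data.frame log (generation, bestVal, meanVal) for
#'   the genetic algorithm; zero rows otherwise.
#'
#' @aliases TuneResult-class
#' @exportClass TuneResult
setClass("TuneResult",
  slots = c(method = "character", metric = "character",
            results = "data.frame", combos = "list",
            trainings = "integer", cacheHits = "integer",
            generations = "data.frame")
)

setMethod("show", "SWD", function(object) {
  cat("SWD object (", object@contrastKind, " design)\n", sep = "")
  cat("  species  :", object@species, "\n")
  cat("  presence :", sum(object@pa == 1L), "records\n")
  cat("  contrast :", sum(object@pa == 0L), "records\n")
  cat("  variables:", paste(colnames(object@data), collapse = ", "), "\n")
})

setMethod("show", "Folds", function(object) {
  cat("Folds (", object@kind, "): k = ", object@k, ", sizes ",
      paste(tabulate(object@assignments, object@k), collapse = "/"),
      "\n", sep = "")
})

setMethod("show", "GridStack", function(object) {
  d <- dim(object@layers[[1L]])
  cat("GridStack:", length(object@layers), "layers,",
      d[1L], "x", d[2L], "cells\n")
  cat("  layers:", paste(names(object@layers), collapse = ", "), "\n")
})

setMethod("show", "TrainedSDM", function(object) {
  cat("TrainedSDM —", object@method, "\n")
  hp <- vapply(object@hypers, function(x) paste(x, collapse = ""), "")
  cat("  hyperparameters:",
      paste(names(hp), hp, sep = "=", collapse = ", "), "\n")
  cat("  training data  :", sum(object@swd@pa == 1L), "presence /",
      sum(object@swd@pa == 0L), object@swd@contrastKind, "records\n")
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "TuneResult", function(object) {
  cat("TuneResult —", object@method, "tuned by", object@metric, "\n")
  cat("  combinations evaluated:", nrow(object@results),
      "| trainings:", object@trainings,
      "| cache hits:", object@cacheHits, "\n")
  cat("  best combination:\n")
  print(utils::head(object@results, 1L))
})

setMethod("show", "HyperGrid", function(object) {
  cat("HyperGrid —", object@method, ":",
      prod(vapply(object@domains, length, 1L)), "combinations\n")
  for (nm in names(object@domains))
    cat("  ", nm, ": ", paste(object@domains[[nm]], collapse = ", "),
        "\n", sep = "")
})
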