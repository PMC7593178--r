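# Virtual-species simulator: smooth correlated environmental layers, a
# known logistic suitability surface, and presence / absence /
# background samples drawn from it.  Provides ground truth for every
# downstream test of the modeling, selection and tuning machinery.

#' Configure a virtual species
#'
#' Defaults describe the standard study conditions used throughout the
#' package tests: an 80 x 80 landscape, three smooth standardized layers
#' of which two carry signal (coefficients 3 and -2), an intercept of -4
#' (a localized species occupying roughly 15 percent of the landscape,
#' as typical of presence-only studies), and 500 presences, 500 absences
#' and 2000 background points.
#'
#' @param rows,cols landscape dimension in cells.
#' @param nLayers number of environmental layers.
#' @param coefs suitability coefficient per layer (length nLayers;
#'   0 = uninformative).
#' @param intercept suitability intercept.
#' @param duplicates optional data.frame(layer, source, sd): layer
#'   \code{layer} becomes layer \code{source} plus Gaussian noise with
#'   the given sd (a controlled collinear pair).
#' @param noiseLayers optional integer indices of layers generated as
#'   unsmoothed white noise (a pure-noise covariate with no spatial
#'   structure; smooth layers with coefficient 0 still carry spatial
#'   chance-structure within one landscape realization).
#' @param smoothness autocorrelation length of the random fields, cells.
#' @param nPresence,nAbsence,nBackground sample sizes.
#' @param seed integer seed.
#' @return a \linkS4class{VirtualSpeciesConfig}.
#' @export
vspConfig <- function(rows = 80, cols = 80, nLayers = 3,
                      coefs = c(3, -2, 0), intercept = -4,
                      duplicates = NULL, noiseLayers = integer(),
                      smoothness = 5,
                      nPresence = 500, nAbsence = 500,
                      nBackground = 2000, seed = 1) {
  if (is.null(duplicates))
    duplicates <- data.frame(layer = integer(), source = integer(),
                             sd = numeric())
  new("VirtualSpeciesConfig", rows = as.integer(rows),
      cols = as.integer(cols), nLayers = as.integer(nLayers),
      coefs = as.numeric(coefs), intercept = as.numeric(intercept),
      duplicates = duplicates, noiseLayers = as.integer(noiseLayers),
      smoothness = as.numeric(smoothness),
      nPresence = as.integer(nPresence), nAbsence = as.integer(nAbsence),
      nBackground = as.integer(nBackground), seed = as.integer(seed))
}

# Smooth random field: white noise circularly convolved with an
# isotropic Gaussian kernel of width `smoothness` cells (via FFT), then
# standardized to mean 0, sd 1.
.smoothField <- function(rows, cols, smoothness) {
  noise <- matrix(stats::rnorm(rows * cols), rows, cols)
  dr <- pmin(0:(rows - 1L), rows - 0:(rows - 1L))
  dc <- pmin(0:(cols - 1L), cols - 0:(cols - 1L))
  kern <- exp(-outer(dr^2, dc^2, "+") / (2 * smoothness^2))
  kern <- kern / sum(kern)
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (rows * cols)
  (f - mean(f)) / stats::sd(f)
}

#' Generate the environmental layers of a virtual landscape
#'
#' Each base layer is an independent smooth Gaussian random field,
#' standardized to mean 0 and sd 1; layers listed in
#' \code{duplicates} are replaced by their source layer plus Gaussian
#' noise of the stated sd (then left unstandardized so that sd 0 means
#' bit-identical).  Reproducible: two calls with the same config give
#' identical stacks.
#'
#' @param config a \linkS4class{VirtualSpeciesConfig}.
#' @return a \linkS4class{GridStack} with layers \code{x1..xn}.
#' @export
generateLayers <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    layers <- lapply(seq_len(config@nLayers), function(j) {
      f <- .smoothField(config@rows, config@cols, config@smoothness)
      if (j %in% config@noiseLayers) {
        w <- matrix(stats::rnorm(config@rows * config@cols),
                    config@rows, config@cols)
        f <- (w - mean(w)) / stats::sd(w)
      }
      f
    })
    if (nrow(config@duplicates)) {
      for (i in seq_len(nrow(config@duplicates))) {
        d <- config@duplicates[i, ]
        noise <- if (d$sd > 0)
          matrix(stats::rnorm(config@rows * config@cols, sd = d$sd),
                 config@rows, config@cols)
        else 0
        layers[[d$layer]] <- layers[[d$source]] + noise
      }
    }
    names(layers) <- paste0("x", seq_len(config@nLayers))
    gridStack(layers)
  })
}

#' True suitability surface
#'
#' Cellwise logistic suitability
#' \eqn{s = 1 / (1 + \exp(-(b_0 + \sum_j b_j x_j)))} over the stack's
#' layers; values strictly inside (0, 1).
#'
#' @param stack a \linkS4class{GridStack} from \code{\link{generateLayers}}.
#' @param config the matching \linkS4class{VirtualSpeciesConfig}.
#' @return a numeric matrix of suitabilities.
#' @export
trueSuitability <- function(stack, config) {
  eta <- matrix(config@intercept, nrow(stack@layers[[1L]]),
                ncol(stack@layers[[1L]]))
  for (j in seq_len(config@nLayers))
    if (config@coefs[j] != 0)
      eta <- eta + config@coefs[j] * stack@layers[[j]]
  stats::plogis(eta)
}

# cell centres under the unit-cell geotransform
.cellXY <- function(rows, cols, cells) {
  r <- (cells - 1L) %% rows + 1L
  c <- (cells - 1L) %/% rows + 1L
  data.frame(X = c - 0.5, Y = rows - r + 0.5)
}

.cellCovariates <- function(stack, cells) {
  as.data.frame(lapply(stack@layers, function(m) as.vector(m)[cells]))
}

#' Sample a virtual species
#'
#' Presences are drawn without replacement with probability proportional
#' to suitability, absences proportional to (1 - suitability), and
#' background points uniformly without replacement (requesting all cells
#' returns every cell exactly once).  Sample sizes are exact.
#'
#' @param stack a \linkS4class{GridStack}.
#' @param suitability matrix from \code{\link{trueSuitability}}.
#' @param config the \linkS4class{VirtualSpeciesConfig}.
#' @return list with \code{pb} (presence + background
#'   \linkS4class{SWD}) and \code{pa} (presence + absence
#'   \linkS4class{SWD}); both share the same presence records.
#' @export
sampleSpecies <- function(stack, suitability, config) {
  rows <- nrow(suitability); cols <- ncol(suitability)
  ncell <- rows * cols
  s <- as.vector(suitability)
  withSeed(config@seed + 1L, {
    pres <- if (config@nPresence > 0)
      sample.int(ncell, config@nPresence, prob = s) else integer()
    abs_ <- if (config@nAbsence > 0)
      sample.int(ncell, config@nAbsence, prob = 1 - s) else integer()
    bg <- if (config@nBackground == ncell) seq_len(ncell)
    else if (config@nBackground > 0)
      sample.int(ncell, config@nBackground) else integer()
    mk <- function(contrast, kind) {
      cells <- c(pres, contrast)
      SWD("virtual_species", .cellXY(rows, cols, cells),
          c(rep(1L, length(pres)), rep(0L, length(contrast))),
          .cellCovariates(stack, cells), kind)
    }
    list(pb = mk(bg, "background"), pa = mk(abs_, "absence"))
  })
}

#' One-shot virtual species simulation
#'
#' Convenience wrapper: generates the layers, the suitability surface
#' and the samples in one call.
#'
#' @param config a \linkS4class{VirtualSpeciesConfig}.
#' @return list(stack, suitability, pb, pa, config).
#' @export
simulateSpecies <- function(config = vspConfig()) {
  stack <- generateLayers(config)
  suit <- trueSuitability(stack, config)
  out <- sampleSpecies(stack, suit, config)
  list(stack = stack, suitability = suit, pb = out$pb, pa = out$pa,
       config = config)
}

#' Write / read a GridStack as single-band TIFF files
#'
#' One 32-bit TIFF per layer plus a JSON sidecar (\code{stack.json})
#' holding layer order, per-layer min/max (samples are stored min-max
#' scaled to [0, 1]) and the unit-cell geotransform, so a stack
#' round-trips through disk.
#'
#' @param stack a \linkS4class{GridStack}.
#' @param dir output directory (created if needed).
#' @return invisibly, the sidecar path.
#' @export
writeGridStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(geotransform = c(0, 1, 0, nrow(stack@layers[[1L]]), 0, -1),
               layers = list())
  for (nm in names(stack@layers)) {
    m <- stack@layers[[nm]]
    lo <- min(m, na.rm = TRUE); hi <- max(m, na.rm = TRUE)
    scaled <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
    scaled[is.na(scaled)] <- 0
    tiff::writeTIFF(scaled, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 32L)
    meta$layers[[nm]] <- list(file = paste0(nm, ".tif"), min = lo, max = hi,
                              na = which(is.na(m)))
  }
  side <- file.path(dir, "stack.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname writeGridStack
#' @param dir directory holding \code{stack.json} and the layer TIFFs.
#' @export
readGridStack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  layers <- lapply(names(meta$layers), function(nm) {
    li <- meta$layers[[nm]]
    m <- tiff::readTIFF(file.path(dir, li$file))
    m <- m * (li$max - li$min) + li$min
    if (length(li$na)) m[li$na] <- NA_real_
    m
  })
  names(layers) <- names(meta$layers)
  gridStack(layers)
}
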