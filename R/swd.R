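# SWD container: accessors, delimited-text I/O, partitioning.

#' @describeIn SWD number of records.
#' @param x,object an \code{SWD} object.
#' @export
nRecords <- function(x) length(x@pa)

#' @describeIn SWD number of presence records.
#' @export
nPresence <- function(x) sum(x@pa == 1L)

#' @describeIn SWD number of contrast (background/absence) records.
#' @export
nContrast <- function(x) sum(x@pa == 0L)

#' @describeIn SWD ordered environmental variable names.
#' @export
variableNames <- function(x) colnames(x@data)

#' @describeIn SWD species label.
#' @export
speciesName <- function(x) x@species

#' @describeIn SWD kind of contrast records ("background" or "absence").
#' @export
contrastKind <- function(x) x@contrastKind

#' @describeIn SWD covariate values (data.frame, one row per record).
#' @export
swdData <- function(x) x@data

#' @describeIn SWD record coordinates (data.frame X, Y).
#' @export
swdCoords <- function(x) x@coords

#' Subset an SWD by records and/or variables
#'
#' @param x an \linkS4class{SWD}.
#' @param records integer or logical index of records to keep.
#' @param variables character vector of variable names to keep.
#' @return the subset \linkS4class{SWD}; record and variable order are
#'   preserved as requested.
#' @export
swdSubset <- function(x, records = NULL, variables = NULL) {
  if (is.null(records)) records <- seq_along(x@pa)
  if (is.null(variables)) variables <- colnames(x@data)
  miss <- setdiff(variables, colnames(x@data))
  if (length(miss))
    stop("unknown variable(s): ", paste(miss, collapse = ", "))
  SWD(x@species, x@coords[records, , drop = FALSE], x@pa[records],
      x@data[records, variables, drop = FALSE], x@contrastKind)
}

#' Merge two SWD objects row-wise
#'
#' Used to refit the final model on the full dataset (training plus
#' validation) before test-set scoring.  Both objects must share species,
#' variables and contrast kind.
#'
#' @param a,b \linkS4class{SWD} objects.
#' @return the concatenated \linkS4class{SWD}.
#' @export
mergeSWD <- function(a, b) {
  if (!identical(colnames(a@data), colnames(b@data)))
    stop("cannot merge SWD objects with different variables")
  if (!identical(a@contrastKind, b@contrastKind))
    stop("cannot merge SWD objects with different contrast kinds")
  SWD(a@species, rbind(a@coords, b@coords), c(a@pa, b@pa),
      rbind(a@data, b@data), a@contrastKind)
}

.checkRect <- function(path) {
  nf <- utils::count.fields(path, sep = ",", quote = "\"", blank.lines.skip = FALSE)
  nf <- nf[!is.na(nf)]
  if (length(nf) < 2L)
    stop("format error in '", path, "': need a header line and at least one record")
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop("format error in '", path, "': line ", bad[1L] + 0L,
         " has ", nf[bad[1L]], " fields, expected ", nf[1L])
}

.readOneSWD <- function(path) {
  .checkRect(path)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  need <- c("species", "X", "Y")
  if (!all(need %in% colnames(df)))
    stop("format error in '", path,
         "': header must contain species, X, Y")
  df
}

#' Read a samples-with-data (SWD) file
#'
#' The dialect is comma-delimited with header
#' \code{species,X,Y,var1,...} (two-file layout: one file of presences,
#' one of contrasts) or \code{species,X,Y,pa,var1,...} (single-file
#' layout with a binary label column \code{pa}).  Empty cells and the
#' token \code{NA} are read as missing covariate values.
#'
#' @param path path to the SWD file (single-file layout, or the presence
#'   file of a two-file layout).
#' @param contrastKind \code{"background"} or \code{"absence"}.
#' @param contrastPath optional path of the contrast file (two-file
#'   layout).
#' @return an \linkS4class{SWD}, record order and variable order
#'   preserved.
#' @export
readSWD <- function(path, contrastKind = "background", contrastPath = NULL) {
  df <- .readOneSWD(path)
  if (!is.null(contrastPath)) {
    bg <- .readOneSWD(contrastPath)
    if (!identical(colnames(df), colnames(bg)))
      stop("presence and contrast files have different headers")
    pa <- c(rep(1L, nrow(df)), rep(0L, nrow(bg)))
    df <- rbind(df, bg)
  } else if ("pa" %in% colnames(df)) {
    pa <- as.integer(df$pa)
    df <- df[, setdiff(colnames(df), "pa"), drop = FALSE]
  } else {
    pa <- rep(1L, nrow(df))
  }
  vars <- setdiff(colnames(df), c("species", "X", "Y"))
  if (length(vars) == 0L)
    stop("schema error in '", path, "': no environmental variables")
  SWD(df$species[1L], df[, c("X", "Y")], pa,
      df[, vars, drop = FALSE], contrastKind)
}

#' Write an SWD object to a delimited-text file
#'
#' Single-file layout with a binary \code{pa} label column; numeric
#' formatting is locale-independent (dot decimal, 17 significant digits
#' so the file re-reads to an identical table); missing covariates are
#' written as the literal token \code{NA}.
#'
#' @param x an \linkS4class{SWD}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSWD <- function(x, path) {
  validObject(x)
  fmt <- function(v) {
    out <- vapply(v, function(z)
      if (is.na(z)) "NA" else sprintf("%.17g", z), "")
    out
  }
  df <- data.frame(species = rep(x@species, length(x@pa)),
                   X = fmt(x@coords$X), Y = fmt(x@coords$Y),
                   pa = x@pa, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (v in colnames(x@data)) df[[v]] <- fmt(x@data[[v]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified hold-out split
#'
#' Presence and contrast records are split independently, so both
#' partitions keep the class balance.  Per-class test size is
#' \code{round(n_class * testFraction)} with halves rounded down.
#'
#' @param x an \linkS4class{SWD}.
#' @param testFraction fraction of each class assigned to the second
#'   (test) partition, in (0, 1).
#' @param seed integer seed; the split is a pure function of
#'   (x, testFraction, seed).
#' @return list with elements \code{train} and \code{test}.
#' @export
splitHoldout <- function(x, testFraction, seed = 1) {
  if (!is.numeric(testFraction) || testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0, 1)")
  idxP <- which(x@pa == 1L)
  idxC <- which(x@pa == 0L)
  if (!length(idxP) || !length(idxC))
    stop("both classes must be non-empty")
  pick <- function(idx) {
    nTest <- roundHalfDown(length(idx) * testFraction)
    sort(sample(idx, nTest))
  }
  test <- withSeed(seed, c(pick(idxP), pick(idxC)))
  train <- setdiff(seq_along(x@pa), test)
  list(train = swdSubset(x, records = train),
       test = swdSubset(x, records = sort(test)))
}

#' Random class-stratified k folds
#'
#' Presences and contrasts are partitioned independently into k
#' near-equal folds (within-class fold sizes differ by at most one), so
#' every fold holds both classes.
#'
#' @param x an \linkS4class{SWD}.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return a \linkS4class{Folds} object.
#' @export
randomFolds <- function(x, k, seed = 1) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  idxP <- which(x@pa == 1L)
  idxC <- which(x@pa == 0L)
  if (length(idxP) < k || length(idxC) < k)
    stop("each class needs at least k records")
  assignments <- integer(length(x@pa))
  withSeed(seed, {
    assignments[idxP] <- rep_len(seq_len(k), length(idxP))[sample(length(idxP))]
    assignments[idxC] <- rep_len(seq_len(k), length(idxC))[sample(length(idxC))]
  })
  new("Folds", kind = "random", assignments = assignments, k = k,
      seed = as.integer(seed))
}

#' Wrap externally constructed folds
#'
#' Accepts per-record fold ids built outside the package (for example
#' spatial blocks) and validates that every fold contains both classes.
#' Ids are relabelled 1..k in order of first appearance.
#'
#' @param x an \linkS4class{SWD}.
#' @param foldIds vector of fold ids, one per record, or the path of a
#'   single-column CSV aligned to record order.
#' @return a \linkS4class{Folds} object.
#' @export
importFolds <- function(x, foldIds) {
  if (is.character(foldIds) && length(foldIds) == 1L)
    foldIds <- utils::read.csv(foldIds)[[1L]]
  if (length(foldIds) != length(x@pa))
    stop("foldIds has ", length(foldIds), " entries but the table has ",
         length(x@pa), " records")
  lv <- unique(foldIds)
  assignments <- match(foldIds, lv)
  k <- length(lv)
  if (k < 2L) stop("need at least 2 distinct folds")
  for (i in seq_len(k)) {
    inFold <- assignments == i
    if (!any(x@pa[inFold] == 1L) || !any(x@pa[inFold] == 0L))
      stop("fold ", lv[i], " does not contain both classes")
  }
  new("Folds", kind = "imported", assignments = as.integer(assignments),
      k = as.integer(k), seed = NA_integer_)
}
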