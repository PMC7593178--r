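# Hyperparameter tuners: exhaustive grid search, random search, and a
# genetic algorithm (population-based: fitness-ranked selection with an
# underfitting guard, single-child crossover, optional mutation drawn
# from the values not carried by either parent).

#' Define a hyperparameter grid
#'
#' @param method model method (ANN, BRT, RF, ME).
#' @param ... named candidate-value vectors, one per hyperparameter;
#'   every name must belong to the method's schema
#'   (\code{\link{hyperSchema}}) and every domain must be nonempty.
#'   Unlisted hyperparameters keep their defaults.
#' @return a \linkS4class{HyperGrid}.
#' @export
hyperGrid <- function(method, ...) {
  method <- match.arg(method, .METHODS)
  domains <- lapply(list(...), unlist)
  if (is.null(names(domains)) || any(names(domains) == ""))
    stop("every domain must be named")
  bad <- setdiff(names(domains), names(hyperSchema(method)))
  if (length(bad))
    stop("unknown hyperparameter(s) for ", method, ": ",
         paste(bad, collapse = ", "))
  if (any(vapply(domains, length, 1L) == 0L))
    stop("every domain must be nonempty")
  new("HyperGrid", method = method, domains = domains)
}

#' @describeIn hyperGrid total number of combinations in the grid.
#' @param grid a \linkS4class{HyperGrid}.
#' @export
nCombos <- function(grid) prod(vapply(grid@domains, length, 1L))

# decode combination `index` (1-based) of the Cartesian product into a
# named hyperparameter list (mixed-radix, first domain varying fastest)
.comboFromIndex <- function(grid, index) {
  sizes <- vapply(grid@domains, length, 1L)
  idx <- index - 1L
  combo <- list()
  for (j in seq_along(sizes)) {
    combo[[names(grid@domains)[j]]] <- grid@domains[[j]][idx %% sizes[j] + 1L]
    idx <- idx %/% sizes[j]
  }
  combo
}

.comboKey <- function(combo)
  paste(names(combo), vapply(combo, as.character, ""), sep = "=",
        collapse = ";")

# Shared evaluation engine with memoization by combo identity: a combo
# requested twice (duplicated offspring) is served from the cache and
# logged as a cache hit, never refitted.
.newTuneState <- function(x, method, metric, val, folds, seed) {
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$trainings <- 0L
  env$cacheHits <- 0L
  env$evaluate <- function(combo) {
    key <- .comboKey(combo)
    env$trainings <- env$trainings + 1L
    if (!is.null(env$cache[[key]])) {
      env$cacheHits <- env$cacheHits + 1L
      return(env$cache[[key]])
    }
    ev <- evaluateModel(x, method, combo, metric, val = val,
                        folds = folds, seed = seed)
    out <- c(train = ev$train, val = ev$validation)
    env$cache[[key]] <- out
    out
  }
  env
}

#' Rank evaluated combinations by fitness
#'
#' For AUC/TSS the primary key is the underfitting flag — combinations
#' whose validation score exceeds their training score rank last — then
#' validation score descending, training score descending, insertion
#' order.  For AICc the ranking is simply ascending AICc (no validation
#' partition exists, so no underfitting rule).
#'
#' @param train,val numeric vectors of training and validation scores.
#' @param metric the evaluation metric.
#' @return integer permutation ordering the combinations best first.
#' @export
rankFitness <- function(train, val, metric = "auc") {
  if (metric == "aicc") return(order(train))
  underfit <- val > train
  order(underfit, -val, -train, seq_along(train))
}

.tuneResult <- function(method, metric, combos, scores, state,
                        generations = NULL) {
  train <- vapply(scores, `[[`, 0, "train")
  val <- vapply(scores, `[[`, 0, "val")
  ord <- rankFitness(train, val, metric)
  df <- do.call(rbind, lapply(combos, function(cb)
    as.data.frame(cb, stringsAsFactors = FALSE)))
  df$train <- train
  df$validation <- val
  if (metric != "aicc") df$underfit <- val > train
  new("TuneResult", method = method, metric = metric,
      results = df[ord, , drop = FALSE], combos = combos[ord],
      trainings = state$trainings, cacheHits = state$cacheHits,
      generations = if (is.null(generations))
        data.frame(generation = integer(), bestVal = numeric(),
                   meanVal = numeric())
      else generations)
}

#' Exhaustive grid search
#'
#' Trains and evaluates every combination of the grid exactly once and
#' ranks them with \code{\link{rankFitness}}.
#'
#' @param x training \linkS4class{SWD}.
#' @param grid a \linkS4class{HyperGrid}.
#' @param metric \code{"auc"}, \code{"tss"} or \code{"aicc"}.
#' @param val,folds validation design (AUC/TSS).
#' @param seed integer seed used for every model training.
#' @return a \linkS4class{TuneResult}.
#' @export
gridSearch <- function(x, grid, metric = "auc", val = NULL, folds = NULL,
                       seed = 1) {
  metric <- .checkMetric(metric)
  total <- nCombos(grid)
  if (total < 1L) stop("empty grid")
  state <- .newTuneState(x, grid@method, metric, val, folds, seed)
  combos <- lapply(seq_len(total), function(i) .comboFromIndex(grid, i))
  scores <- vector("list", total)
  for (i in seq_len(total)) {
    scores[[i]] <- state$evaluate(combos[[i]])
    logStep("gridSearch", i, "/", total, " ", .comboKey(combos[[i]]),
            sprintf(" train %.4f val %.4f", scores[[i]]["train"],
                    scores[[i]]["val"]))
  }
  .tuneResult(grid@method, metric, combos, scores, state)
}

#' Random search
#'
#' Evaluates \code{min(populationSize, nCombos(grid))} distinct
#' combinations sampled uniformly without replacement (sampling the
#' whole grid reduces to \code{\link{gridSearch}}).
#'
#' @inheritParams gridSearch
#' @param populationSize number of combinations to sample (default 20).
#' @return a \linkS4class{TuneResult}.
#' @export
randomSearch <- function(x, grid, metric = "auc", val = NULL,
                         folds = NULL, populationSize = 20, seed = 1) {
  metric <- .checkMetric(metric)
  if (populationSize < 1) stop("populationSize must be >= 1")
  total <- nCombos(grid)
  n <- min(populationSize, total)
  idx <- withSeed(seed, sample.int(total, n))
  state <- .newTuneState(x, grid@method, metric, val, folds, seed)
  combos <- lapply(idx, function(i) .comboFromIndex(grid, i))
  scores <- vector("list", n)
  for (i in seq_len(n)) {
    scores[[i]] <- state$evaluate(combos[[i]])
    logStep("randomSearch", i, "/", n, " ", .comboKey(combos[[i]]),
            sprintf(" train %.4f val %.4f", scores[[i]]["train"],
                    scores[[i]]["val"]))
  }
  .tuneResult(grid@method, metric, combos, scores, state)
}

#' Single-child crossover of two hyperparameter combinations
#'
#' Each hyperparameter value is inherited uniformly from one of the two
#' parents; then, with probability \code{mutationChance}, one uniformly
#' chosen hyperparameter is reassigned a uniform draw from its domain
#' excluding both parents' values (mutation is skipped when no third
#' value exists).
#'
#' @param parent1,parent2 named hyperparameter lists over \code{grid}.
#' @param grid the shared \linkS4class{HyperGrid}.
#' @param mutationChance mutation probability in [0, 1].
#' @return the child combination (named list).  Not seeded internally:
#'   the caller owns the RNG stream.
#' @export
crossoverCombo <- function(parent1, parent2, grid, mutationChance = 0.4) {
  nms <- names(grid@domains)
  if (!setequal(names(parent1), nms) || !setequal(names(parent2), nms))
    stop("parents must share the grid's hyperparameters")
  child <- stats::setNames(lapply(nms, function(nm)
    if (stats::runif(1) < 0.5) parent1[[nm]] else parent2[[nm]]), nms)
  if (stats::runif(1) < mutationChance) {
    hp <- nms[sample.int(length(nms), 1L)]
    pool <- setdiff(grid@domains[[hp]], c(parent1[[hp]], parent2[[hp]]))
    if (length(pool))
      child[[hp]] <- pool[sample.int(length(pool), 1L)]
  }
  child
}

#' Genetic-algorithm hyperparameter optimization
#'
#' Starts from a \code{\link{randomSearch}} population; each generation
#' the population is fitness-ranked (\code{\link{rankFitness}}), the top
#' \code{round(size * keepBest)} combinations are retained together with
#' \code{round(size * keepRandom)} drawn uniformly without replacement
#' from the remainder (both rounds are round-half-to-even), and children
#' bred by \code{\link{crossoverCombo}} of two distinct uniformly chosen
#' retained parents refill the population.  Previously evaluated
#' combinations are served from the cache, never refitted.  With zero
#' generations the result equals \code{\link{randomSearch}}.
#'
#' Training requests per run satisfy
#' \code{size + generations * (size - round(size*keepBest) -
#' round(size*keepRandom))} — 60 under the defaults (20, 5, 0.4, 0.2).
#'
#' @inheritParams gridSearch
#' @param populationSize population size (default 20).
#' @param generations number of generations (default 5).
#' @param keepBest fraction of best combinations retained (default 0.4).
#' @param keepRandom fraction of the population size retained at random
#'   from the non-elite remainder (default 0.2).
#' @param mutationChance mutation probability (default 0.4).
#' @return a \linkS4class{TuneResult} holding the final population, the
#'   per-generation fitness log, and the training-request count.
#' @export
optimizeModel <- function(x, grid, metric = "auc", val = NULL,
                          folds = NULL, populationSize = 20,
                          generations = 5, keepBest = 0.4,
                          keepRandom = 0.2, mutationChance = 0.4,
                          seed = 1) {
  metric <- .checkMetric(metric)
  if (keepBest < 0 || keepBest > 1 || keepRandom < 0 || keepRandom > 1)
    stop("keep fractions must be in [0, 1]")
  if (keepBest + keepRandom > 1)
    stop("keepBest + keepRandom must not exceed 1")
  total <- nCombos(grid)
  if (total <= populationSize) {
    logStep("optimizeModel", "grid holds ", total,
            " combinations <= population size; degenerating to gridSearch")
    return(gridSearch(x, grid, metric, val, folds, seed))
  }
  state <- .newTuneState(x, grid@method, metric, val, folds, seed)
  idx <- withSeed(seed, sample.int(total, populationSize))
  pop <- lapply(idx, function(i) .comboFromIndex(grid, i))
  scores <- lapply(seq_along(pop), function(i) {
    sc <- state$evaluate(pop[[i]])
    logStep("optimizeModel", "init ", i, "/", populationSize, " ",
            .comboKey(pop[[i]]),
            sprintf(" train %.4f val %.4f", sc["train"], sc["val"]))
    sc
  })
  nBest <- round(populationSize * keepBest)
  nRand <- round(populationSize * keepRandom)
  nChildren <- populationSize - nBest - nRand
  genLog <- data.frame(generation = integer(), bestVal = numeric(),
                       meanVal = numeric())
  if (generations > 0) withSeed(seed + 1L, {
    for (g in seq_len(generations)) {
      train <- vapply(scores, `[[`, 0, "train")
      val_ <- vapply(scores, `[[`, 0, "val")
      ord <- rankFitness(train, val_, metric)
      elite <- ord[seq_len(nBest)]
      rest <- ord[-seq_len(nBest)]
      lucky <- if (nRand > 0) sample(rest, nRand) else integer()
      keepIdx <- c(elite, lucky)
      pop <- pop[keepIdx]
      scores <- scores[keepIdx]
      parents <- pop  # children are bred from the retained set only
      for (ch in seq_len(nChildren)) {
        par <- sample.int(length(parents), 2L)
        child <- crossoverCombo(parents[[par[1L]]], parents[[par[2L]]],
                                grid, mutationChance)
        sc <- state$evaluate(child)
        pop[[length(pop) + 1L]] <- child
        scores[[length(scores) + 1L]] <- sc
      }
      fv <- vapply(scores, `[[`, 0, "val")
      ft <- vapply(scores, `[[`, 0, "train")
      bestVal <- if (metric == "aicc") min(ft) else
        fv[rankFitness(ft, fv, metric)[1L]]
      genLog <- rbind(genLog, data.frame(
        generation = g, bestVal = bestVal,
        meanVal = mean(if (metric == "aicc") ft else fv)))
      logStep("optimizeModel", "generation ", g, "/", generations,
              sprintf(": best %.4f mean %.4f", bestVal,
                      genLog$meanVal[g]))
    }
  })
  expected <- as.integer(populationSize +
                           max(0, generations) * nChildren)
  stopifnot(state$trainings == expected)
  .tuneResult(grid@method, metric, pop, scores, state, genLog)
}

#' Serialize a tuning result
#'
#' Writes the ranked results table as CSV and a JSON log with metric,
#' method, training counts and the per-generation fitness trace.
#'
#' @param result a \linkS4class{TuneResult}.
#' @param csvPath,jsonPath output paths (either may be NULL to skip).
#' @export
writeTuneResult <- function(result, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(result@results, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(
      method = result@method, metric = result@metric,
      trainings = result@trainings, cacheHits = result@cacheHits,
      best = result@combos[[1L]],
      generations = result@generations,
      results = result@results), jsonPath, auto_unbox = TRUE,
      digits = NA, dataframe = "rows")
  invisible(result)
}

#' Read a tuning configuration file
#'
#' YAML with fields: \code{method}, \code{metric}, \code{algorithm}
#' (grid | random | genetic), \code{grid} (hyperparameter -> candidate
#' list), optional \code{validation} (\code{type: holdout, fraction}
#' or \code{type: kfold, k}), optional \code{ga} settings (size,
#' generations, keepBest, keepRandom, mutation), and \code{seed}.
#'
#' @param path YAML file path.
#' @return validated named list with a \linkS4class{HyperGrid} in
#'   \code{$grid}.
#' @export
readTuneConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("method", "grid"))
    if (is.null(cfg[[f]])) stop("tuning config misses field '", f, "'")
  cfg$method <- toupper(cfg$method)
  cfg$metric <- tolower(cfg$metric %||% "auc")
  cfg$algorithm <- match.arg(cfg$algorithm %||% "genetic",
                             c("grid", "random", "genetic"))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  ga <- cfg$ga %||% list()
  cfg$ga <- list(size = ga$size %||% 20, generations = ga$generations %||% 5,
                 keepBest = ga$keepBest %||% 0.4,
                 keepRandom = ga$keepRandom %||% 0.2,
                 mutation = ga$mutation %||% 0.4)
  cfg$grid <- do.call(hyperGrid, c(list(method = cfg$method), cfg$grid))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
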