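test_that("grids validate names and count combinations", {
  g <- hyperGrid("ME", fc = c("l", "lq", "lqp"), reg = c(0.5, 1))
  expect_equal(nCombos(g), 6)
  expect_error(hyperGrid("ME", bogus = 1), "unknown hyperparameter")
  expect_error(hyperGrid("ME", fc = character()), "nonempty")
  combos <- lapply(1:6, function(i) habtune:::.comboFromIndex(g, i))
  keys <- vapply(combos, habtune:::.comboKey, "")
  expect_equal(length(unique(keys)), 6L)  # decoding is a bijection
})

test_that("grid search evaluates every combination exactly once", {
  sim <- tinySim()
  sp <- splitHoldout(sim$pb, 0.25, seed = 2)
  g <- hyperGrid("ME", fc = c("l", "lq", "lqp"), reg = c(0.5, 1))
  res <- gridSearch(sp$train, g, "auc", val = sp$test, seed = 2)
  expect_equal(res@trainings, 6L)
  expect_equal(nrow(res@results), 6L)
  expect_equal(res@cacheHits, 0L)
  # a single-combination grid returns itself as the best
  g1 <- hyperGrid("ME", fc = "l")
  res1 <- gridSearch(sp$train, g1, "auc", val = sp$test, seed = 2)
  expect_equal(nrow(res1@results), 1L)
  expect_identical(res1@combos[[1L]]$fc, "l")
})

test_that("random search samples distinct combos, deterministically", {
  sim <- tinySim()
  sp <- splitHoldout(sim$pb, 0.25, seed = 2)
  g <- hyperGrid("ME", fc = c("l", "lq"), reg = c(0.3, 1, 3),
                 iter = c(300, 500))
  a <- randomSearch(sp$train, g, "auc", val = sp$test,
                    populationSize = 5, seed = 4)
  b <- randomSearch(sp$train, g, "auc", val = sp$test,
                    populationSize = 5, seed = 4)
  keys <- function(r) sort(vapply(r@combos, habtune:::.comboKey, ""))
  expect_equal(a@trainings, 5L)
  expect_equal(length(unique(keys(a))), 5L)
  expect_identical(keys(a), keys(b))
  # requesting at least the whole grid degenerates to grid search
  full <- randomSearch(sp$train, g, "auc", val = sp$test,
                       populationSize = 99, seed = 4)
  expect_equal(full@trainings, nCombos(g))
})

test_that("fitness ranking demotes underfit configurations", {
  # B has the better validation score but is underfit (val > train)
  ord <- rankFitness(train = c(0.9, 0.7), val = c(0.8, 0.75))
  expect_equal(ord, c(1L, 2L))
  # among flagged combos, validation still decides
  ordAll <- rankFitness(train = c(0.5, 0.5), val = c(0.6, 0.7))
  expect_equal(ordAll, c(2L, 1L))
  # equal validation: higher train first
  ordTie <- rankFitness(train = c(0.85, 0.9), val = c(0.8, 0.8))
  expect_equal(ordTie, c(2L, 1L))
  # AICc ranks ascending with no underfit rule
  expect_equal(rankFitness(train = c(300, 250), val = c(NA, NA),
                           metric = "aicc"), c(2L, 1L))
})

test_that("crossover inherits uniformly and respects domain exclusions", {
  g <- hyperGrid("ME", fc = c("l", "lq", "lqp", "lqph"),
                 reg = c(0.5, 1, 2), iter = c(300, 500))
  p1 <- list(fc = "l", reg = 0.5, iter = 300)
  p2 <- list(fc = "lq", reg = 1, iter = 500)
  # identical parents, no mutation -> child is the parent
  set.seed(1)
  expect_identical(crossoverCombo(p1, p1, g, mutationChance = 0),
                   p1[names(g@domains)])
  # a mutated hyperparameter never takes a parent's value; domains of
  # size 2 have no third value, so iter can only come from a parent
  set.seed(2)
  for (i in 1:200) {
    ch <- crossoverCombo(p1, p2, g, mutationChance = 1)
    expect_true(ch$iter %in% c(300, 500))
    mutated <- c(!ch$fc %in% c("l", "lq"), !ch$reg %in% c(0.5, 1))
    expect_lte(sum(mutated), 1L)
  }
  # uniform inheritance: each hyperparameter matches parent1 in
  # 50% +/- 2% of 10000 draws when mutation is off
  set.seed(3)
  hits <- c(fc = 0, reg = 0, iter = 0)
  for (i in 1:10000) {
    ch <- crossoverCombo(p1, p2, g, mutationChance = 0)
    hits <- hits + c(ch$fc == p1$fc, ch$reg == p1$reg,
                     ch$iter == p1$iter)
  }
  expect_true(all(abs(hits / 10000 - 0.5) < 0.02))
  expect_error(crossoverCombo(p1, list(a = 1), g), "share the grid")
})

test_that("the genetic algorithm honours its training budget and cache", {
  sim <- tinySim()
  sp <- splitHoldout(sim$pb, 0.25, seed = 2)
  g <- hyperGrid("ME", fc = c("l", "lq"), reg = c(0.3, 0.7, 1, 2, 4),
                 iter = c(200, 300, 500))
  res <- optimizeModel(sp$train, g, "auc", val = sp$test,
                       populationSize = 10, generations = 3,
                       keepBest = 0.4, keepRandom = 0.2, seed = 6)
  expect_equal(res@trainings, 10L + 3L * (10L - 4L - 2L))  # 22
  # actual fits (requests minus cache hits) cannot exceed the number of
  # distinct combinations in the grid
  expect_lte(res@trainings - res@cacheHits, nCombos(g))
  expect_equal(nrow(res@generations), 3L)
  # elitism: the best retained fitness never degrades
  expect_true(all(diff(res@generations$bestVal) >= -1e-12))
  # the whole run is a pure function of the seed
  res2 <- optimizeModel(sp$train, g, "auc", val = sp$test,
                        populationSize = 10, generations = 3,
                        keepBest = 0.4, keepRandom = 0.2, seed = 6)
  expect_identical(res2@results, res@results)
  expect_identical(res2@cacheHits, res@cacheHits)
  expect_error(optimizeModel(sp$train, g, keepBest = 0.8,
                             keepRandom = 0.4, val = sp$test),
               "not exceed 1")
})

test_that("zero generations reduce the GA to random search", {
  sim <- tinySim()
  sp <- splitHoldout(sim$pb, 0.25, seed = 2)
  g <- hyperGrid("ME", fc = c("l", "lq"), reg = c(0.3, 0.7, 1, 2, 4),
                 iter = c(200, 300, 500))
  ga <- optimizeModel(sp$train, g, "auc", val = sp$test,
                      populationSize = 8, generations = 0, seed = 9)
  rs <- randomSearch(sp$train, g, "auc", val = sp$test,
                     populationSize = 8, seed = 9)
  keys <- function(r) sort(vapply(r@combos, habtune:::.comboKey, ""))
  expect_identical(keys(ga), keys(rs))
  expect_equal(ga@trainings, 8L)
})

test_that("tuning configs round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("method: ME", "metric: auc", "algorithm: random",
               "grid:", "  fc: [l, lq]", "  reg: [0.5, 1]",
               "validation: {type: holdout, fraction: 0.25}",
               "seed: 12"), f)
  cfg <- readTuneConfig(f)
  expect_identical(cfg$algorithm, "random")
  expect_s4_class(cfg$grid, "HyperGrid")
  expect_equal(nCombos(cfg$grid), 4)
  expect_equal(cfg$ga$size, 20)          # defaults fill the gaps
  writeLines(c("method: ME"), f)
  expect_error(readTuneConfig(f), "misses field")
})

test_that("tuning results serialize to CSV and JSON sidecars", {
  sim <- tinySim()
  sp <- splitHoldout(sim$pb, 0.25, seed = 2)
  g <- hyperGrid("ME", fc = c("l", "lq"))
  res <- gridSearch(sp$train, g, "auc", val = sp$test, seed = 2)
  d <- withr::local_tempdir()
  writeTuneResult(res, file.path(d, "t.csv"), file.path(d, "t.json"))
  back <- read.csv(file.path(d, "t.csv"))
  expect_equal(nrow(back), 2L)
  js <- jsonlite::read_json(file.path(d, "t.json"))
  expect_equal(js$trainings, 2L)
  expect_identical(js$best$fc, res@combos[[1L]]$fc)
})
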