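test_that("rank correlations behave like Spearman's rho", {
  x <- randomSWD(n = 60, p = 2, seed = 5)
  x@data$v3 <- exp(x@data$v1)   # monotone map: rho exactly 1
  x@data$v4 <- -x@data$v1
  cm <- swdCor(x)
  expect_equal(diag(cm), setNames(rep(1, 4), colnames(cm)))
  expect_equal(cm["v1", "v3"], 1)
  expect_equal(cm["v1", "v4"], -1)
  expect_warning(swdCor(x, sample = 1e6), "using all")
  expect_error(swdCor(swdSubset(x, variables = "v1")), "two variables")
})

test_that("varSel removes exactly one member of a near-duplicate pair", {
  for (seed in c(11, 12, 13)) {
    sim <- dupSim(seed)
    res <- varSel(sim$pb, "ME", list(fc = "lq"), corThreshold = 0.7,
                  seed = seed)
    removed <- res$trace$removed
    expect_equal(nrow(res$trace), 1L)           # one step, one variable
    expect_true(removed %in% c("x1", "x4"))
    expect_equal(sort(c(removed, res$retained)),
                 paste0("x", 1:4))               # partition invariant
    cm <- swdCor(swdSubset(sim$pb, variables = res$retained))
    diag(cm) <- 0
    expect_lt(max(abs(cm)), 0.7)                 # postcondition
    expect_equal(res$trace$reason, "collinear")
  }
})

test_that("varSel is a no-op when nothing is correlated", {
  sim <- tinySim()
  res <- varSel(sim$pb, "ME", list(fc = "l"), corThreshold = 0.99,
                seed = 1)
  expect_equal(nrow(res$trace), 0L)
  expect_identical(res$retained, variableNames(sim$pb))
})

test_that("three mutual duplicates need exactly two removals", {
  cfg <- vspConfig(rows = 50, cols = 50, nLayers = 5,
                   coefs = c(3, -2, 0, 0, 0),
                   duplicates = data.frame(layer = c(4, 5),
                                           source = c(1, 1),
                                           sd = c(0.05, 0.05)),
                   nPresence = 120, nAbsence = 120, nBackground = 300,
                   seed = 19)
  sim <- simulateSpecies(cfg)
  res <- varSel(sim$pb, "ME", list(fc = "l"), corThreshold = 0.7,
                seed = 3)
  expect_equal(nrow(res$trace), 2L)
  expect_equal(length(res$retained), 3L)
  expect_equal(length(intersect(res$retained, c("x1", "x4", "x5"))), 1L)
})

test_that("reduceVar honours its threshold edge cases", {
  sim <- tinySim()
  sp <- splitHoldout(sim$pb, 0.25, seed = 4)
  none <- reduceVar(sp$train, "ME", list(fc = "l"), threshold = 0,
                    useJackknife = FALSE, seed = 4)
  expect_equal(nrow(none$trace), 0L)      # nothing is below 0%
  all_ <- reduceVar(sp$train, "ME", list(fc = "l"), threshold = 100,
                    useJackknife = FALSE, seed = 4)
  expect_equal(length(all_$retained), 1L) # keeps at least one variable
  expect_equal(nrow(all_$trace), 2L)
  expect_error(reduceVar(sp$train, "ME", threshold = 2,
                         useJackknife = TRUE),
               "validation design")
})

test_that("jackknife reduction drops noise without losing validation skill", {
  for (seed in c(21, 22)) {
    sim <- dupSimFull(seed)
    keep <- c("x1", "x2", "x3")   # x3 is the pure-noise covariate
    swd <- swdSubset(sim$pb, variables = keep)
    sp <- splitHoldout(swd, 0.2, seed = seed)
    before <- evaluateModel(sp$train, "ME", list(fc = "lq"), "auc",
                            val = sp$test, seed = seed)$validation
    res <- reduceVar(sp$train, "ME", list(fc = "lq"), threshold = 2,
                     useJackknife = TRUE, val = sp$test, seed = seed)
    after <- evaluateModel(sp$train |>
                             swdSubset(variables = res$retained), "ME",
                           list(fc = "lq"), "auc",
                           val = sp$test, seed = seed)$validation
    expect_gte(after, before)            # acceptance rule of the variant
    expect_false("x3" %in% res$retained) # the noise variable goes
    expect_true(all(c("x1", "x2") %in% res$retained))
  }
})

test_that("selection traces replay to the final model", {
  sim <- dupSim(31)
  res <- varSel(sim$pb, "ME", list(fc = "lq"), corThreshold = 0.7,
                seed = 5)
  replay <- trainSDM(swdSubset(sim$pb, variables = res$retained), "ME",
                     list(fc = "lq"), seed = 5)
  expect_identical(predict(replay, sim$pb), predict(res$model, sim$pb))
  if (nrow(res$trace))
    expect_equal(res$trace$metricAfter[nrow(res$trace)],
                 habtune:::.scoreMetric(replay,
                   swdSubset(sim$pb, variables = res$retained), "auc"))
})
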