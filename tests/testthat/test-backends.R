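test_that("hyperparameter schemas carry the canonical defaults", {
  me <- hyperSchema("ME")
  expect_identical(me$fc, "lqph")
  expect_identical(me$reg, 1)
  expect_identical(me$iter, 500)
  rf <- hyperSchema("RF")
  expect_identical(rf$n_trees, 500)
  expect_identical(rf$nodesize, 1)
  brt <- hyperSchema("BRT")
  expect_identical(unlist(brt[c("n_trees", "interaction_depth",
                                "shrinkage", "bag_fraction")]),
                   c(n_trees = 100, interaction_depth = 1,
                     shrinkage = 0.1, bag_fraction = 0.5))
  ann <- hyperSchema("ANN")
  expect_identical(unlist(ann[c("decay", "rang", "maxit")]),
                   c(decay = 0, rang = 0.7, maxit = 100))
  expect_identical(meBackgroundCap(), 10000L)
})

test_that("data-dependent defaults resolve as documented", {
  expect_equal(defaultHypers("RF", nVariables = 9)$mtry, 3)
  expect_equal(defaultHypers("RF", nVariables = 10)$mtry, 3)
  expect_equal(defaultHypers("ANN", nVariables = 7)$size, 7)
  expect_error(defaultHypers("ME", list(bogus = 1)),
               "unknown hyperparameter")
})

test_that("the Maxent-style method refuses absence-contrast tables", {
  sim <- tinySim()
  expect_error(trainSDM(sim$pa, "ME"), "background contrast")
})

test_that("raw output is a normalized distribution over the background", {
  sim <- tinySim()
  m <- trainSDM(sim$pb, "ME", list(fc = "lq"), seed = 2)
  raw <- predict(m, sim$pb, type = "raw")
  expect_equal(sum(raw[sim$pb@pa == 0L]), 1, tolerance = 1e-8)
  expect_true(all(predict(m, sim$pb) >= 0 & predict(m, sim$pb) <= 1))
})

test_that("an infinite penalty collapses to the null model", {
  sim <- tinySim()
  m <- trainSDM(sim$pb, "ME", list(fc = "lq", reg = 1e8), seed = 2)
  expect_true(all(m@coefs[-1L] == 0))
  raw <- predict(m, sim$pb, type = "raw")
  nbg <- nContrast(sim$pb)
  expect_equal(raw[sim$pb@pa == 0L], rep(1 / nbg, nbg), tolerance = 1e-12)
})

test_that("validation score spread shrinks as the multiplier grows", {
  sim <- tinySim()
  sp <- splitHoldout(sim$pb, 0.3, seed = 7)
  spread <- vapply(c(0.5, 2, 20), function(reg) {
    m <- trainSDM(sp$train, "ME", list(fc = "lq", reg = reg), seed = 2)
    r <- predict(m, sp$test, type = "raw")
    max(r) - min(r)
  }, 0)
  expect_true(all(diff(spread) <= 1e-12))
})

test_that("covariates beyond the training range are clamped", {
  sim <- tinySim()
  m <- trainSDM(sim$pb, "ME", list(fc = "lq"), seed = 2)
  rng <- m@ranges
  atMax <- as.data.frame(as.list(setNames(rng$max, rng$variable)))
  beyond <- atMax + 10
  expect_equal(predict(m, beyond), predict(m, atMax))
})

test_that("training is deterministic under a fixed seed for all methods", {
  sim <- tinySim()
  probe <- randomSWD(n = 20, p = 3, seed = 99)
  names(probe@data) <- variableNames(sim$pb)
  for (meth in c("ANN", "BRT", "RF")) {
    a <- predict(trainSDM(sim$pa, meth, seed = 5), probe)
    b <- predict(trainSDM(sim$pa, meth, seed = 5), probe)
    expect_identical(a, b)
  }
  a <- predict(trainSDM(sim$pb, "ME", list(fc = "lq"), seed = 5), probe)
  b <- predict(trainSDM(sim$pb, "ME", list(fc = "lq"), seed = 5), probe)
  expect_identical(a, b)
})

test_that("every backend separates a strong-signal species in training", {
  sim <- tinySim()
  for (meth in c("ANN", "BRT", "RF")) {
    m <- trainSDM(sim$pa, meth, seed = 3)
    sc <- predict(m, sim$pa)
    expect_gt(aucFromScores(sc[sim$pa@pa == 1L], sc[sim$pa@pa == 0L]),
              0.75)
  }
})

test_that("prediction demands the training variables by name", {
  sim <- tinySim()
  m <- trainSDM(sim$pb, "ME", list(fc = "l"), seed = 2)
  expect_error(predict(m, data.frame(x1 = 1, x2 = 0)), "x3")
  expect_error(predict(m, sim$pa, type = "raw"), NA)
  m2 <- trainSDM(sim$pa, "RF", seed = 2)
  expect_error(predict(m2, sim$pa, type = "raw"), "Maxent-style")
})

test_that("rows with missing covariates predict NA, others are unaffected", {
  sim <- tinySim()
  m <- trainSDM(sim$pb, "ME", list(fc = "lq"), seed = 2)
  df <- swdData(sim$pb)[1:5, ]
  df$x2[3] <- NA
  sc <- predict(m, df)
  expect_true(is.na(sc[3]))
  expect_equal(sc[-3], predict(m, swdData(sim$pb)[1:5, ])[-3])
})

test_that("non-convergence is recorded on the model, not thrown", {
  sim <- tinySim()
  expect_no_warning(m <- trainSDM(sim$pb, "ME",
                                  list(fc = "lq", iter = 3), seed = 2))
  expect_true(length(m@notes) > 0)
})

test_that("oversized backgrounds are capped for the Maxent-style method", {
  cfg <- vspConfig(rows = 110, cols = 110, nPresence = 100, nAbsence = 10,
                   nBackground = 11000, seed = 13)
  sim <- simulateSpecies(cfg)
  m <- trainSDM(sim$pb, "ME", list(fc = "l"), seed = 4)
  expect_equal(nContrast(m@swd), meBackgroundCap())
  m2 <- trainSDM(sim$pb, "ME", list(fc = "l"), seed = 4)
  expect_identical(swdData(m@swd), swdData(m2@swd))
})

test_that("a saved model archive reproduces predictions bit for bit", {
  sim <- tinySim()
  m <- trainSDM(sim$pb, "ME", list(fc = "lqph"), seed = 2)
  f <- withr::local_tempfile(fileext = ".rds")
  saveSDM(m, f)
  m2 <- loadSDM(f)
  expect_identical(predict(m2, sim$pb), predict(m, sim$pb))
})
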