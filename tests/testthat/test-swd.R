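test_that("SWD files round-trip field by field, including missing cells", {
  for (seed in 1:5) {
    x <- randomSWD(n = 20 + seed, p = 2 + seed %% 2, seed = seed,
                   withNA = seed %% 2 == 0)
    f <- withr::local_tempfile(fileext = ".csv")
    writeSWD(x, f)
    y <- readSWD(f, contrastKind = contrastKind(x))
    expect_identical(speciesName(y), speciesName(x))
    expect_identical(variableNames(y), variableNames(x))
    expect_identical(y@pa, x@pa)
    expect_equal(swdCoords(y), swdCoords(x))
    expect_equal(swdData(y), swdData(x))
  }
})

test_that("a toy presence+background file reads with order preserved", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,X,Y,pa,temp,prec",
               "toy,0.5,0.5,1,10,800", "toy,1.5,0.5,1,12,650",
               "toy,2.5,1.5,0,20,400", "toy,3.5,1.5,0,25,300"), f)
  x <- readSWD(f)
  expect_equal(nRecords(x), 4L)
  expect_identical(variableNames(x), c("temp", "prec"))
  expect_identical(x@pa, c(1L, 1L, 0L, 0L))
  expect_equal(swdData(x)$temp, c(10, 12, 20, 25))
})

test_that("two-file layout concatenates presences then contrasts", {
  fp <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,X,Y,temp", "sp,1,1,10", "sp,2,2,12"), fp)
  writeLines(c("species,X,Y,temp", "sp,3,3,20"), fb)
  x <- readSWD(fp, contrastPath = fb)
  expect_identical(x@pa, c(1L, 1L, 0L))
})

test_that("malformed files fail loudly with the offending line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,X,Y,pa,temp", "a,1,2,1,3", "a,1,2,0"), f)
  expect_error(readSWD(f), "line 3")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,X,Y,pa", "a,1,2,1", "a,1,2,0"), f2)
  expect_error(readSWD(f2), "no environmental variables")
})

test_that("an SWD with zero variables cannot be constructed", {
  expect_error(SWD("a", data.frame(X = 1, Y = 1), 1L,
                   data.frame()[1, , drop = FALSE]),
               "environmental variable")
})

test_that("hold-out splits are stratified, exact and reproducible", {
  x <- randomSWD(n = 200, seed = 3)  # 100 presences, 100 contrasts
  sp <- splitHoldout(x, 0.2, seed = 9)
  expect_equal(nPresence(sp$train), 80L)
  expect_equal(nPresence(sp$test), 20L)
  expect_equal(nContrast(sp$train), 80L)
  expect_equal(nContrast(sp$test), 20L)
  expect_equal(nRecords(sp$train) + nRecords(sp$test), nRecords(x))
  sp2 <- splitHoldout(x, 0.2, seed = 9)
  expect_identical(swdData(sp$test), swdData(sp2$test))
  expect_error(splitHoldout(x, 1.2), "in \\(0, 1\\)")
})

test_that("per-class test size rounds halves down", {
  # 10 presences at fraction 0.25 -> 2.5 -> 2 test presences
  x <- SWD("s", data.frame(X = 1:30, Y = 1:30),
           rep(c(1L, 0L, 0L), 10), data.frame(v = runif(30)))
  sp <- splitHoldout(x, 0.25, seed = 1)
  expect_equal(nPresence(sp$test), 2L)
  expect_equal(nContrast(sp$test), 5L)
})

test_that("random folds are class-stratified with near-equal sizes", {
  set.seed(4)
  x <- SWD("s", data.frame(X = 1:440, Y = 1:440),
           c(rep(1L, 40), rep(0L, 400)), data.frame(v = runif(440)))
  f <- randomFolds(x, 4, seed = 2)
  for (i in 1:4) {
    inFold <- f@assignments == i
    expect_equal(sum(x@pa[inFold] == 1L), 10L)
    expect_equal(sum(x@pa[inFold] == 0L), 100L)
  }
  expect_identical(randomFolds(x, 4, seed = 2)@assignments, f@assignments)
  # pigeonhole: 3 presences over k = 2 folds -> sizes {2, 1}
  y <- SWD("s", data.frame(X = 1:13, Y = 1:13),
           c(rep(1L, 3), rep(0L, 10)), data.frame(v = runif(13)))
  f2 <- randomFolds(y, 2, seed = 1)
  sizes <- sort(tabulate(f2@assignments[y@pa == 1L], 2))
  expect_equal(sizes, c(1L, 2L))
  expect_error(randomFolds(y, 5), "at least k records")
})

test_that("imported folds validate shape and class coverage", {
  x <- randomSWD(n = 40, seed = 6)
  ids <- rep(1:4, each = 10)
  f <- importFolds(x, ids)
  expect_equal(f@k, 4L)
  expect_error(importFolds(x, ids[-1]), "40 records")
  badIds <- rep(1L, 40)                 # fold 2 is all background
  badIds[which(x@pa == 0L)[1:10]] <- 2L
  expect_error(importFolds(x, badIds), "fold 2")
})

test_that("subset and merge are inverse-compatible and validated", {
  x <- randomSWD(n = 20, seed = 8)
  sp <- splitHoldout(x, 0.3, seed = 1)
  m <- mergeSWD(sp$train, sp$test)
  expect_equal(nRecords(m), nRecords(x))
  expect_error(swdSubset(x, variables = "nope"), "unknown variable")
  expect_error(mergeSWD(x, swdSubset(x, variables = "v1")),
               "different variables")
})
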