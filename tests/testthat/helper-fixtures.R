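# Shared fixtures, built in code.  Simulations are memoised so several
# test files can reuse the same landscape without re-generating it.

options(habtune.quiet = TRUE)

.fixtureCache <- new.env(parent = emptyenv())

memoSim <- function(key, config) {
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- simulateSpecies(config)
  .fixtureCache[[key]]
}

# small strong-signal species (two informative layers, one noise)
tinySim <- function(seed = 11) {
  memoSim(paste0("tiny", seed),
          vspConfig(rows = 50, cols = 50, nPresence = 150, nAbsence = 150,
                    nBackground = 400, seed = seed))
}

# species with an injected near-duplicate pair (x4 ~ x1) and an
# injected pure-noise covariate (x3: unsmoothed white noise)
dupSim <- function(seed = 11) {
  memoSim(paste0("dup", seed),
          vspConfig(rows = 50, cols = 50, nLayers = 4,
                    coefs = c(3, -2, 0, 0), noiseLayers = 3L,
                    duplicates = data.frame(layer = 4, source = 1,
                                            sd = 0.05),
                    nPresence = 150, nAbsence = 150, nBackground = 400,
                    seed = seed))
}

# the same design at the full study conditions (default landscape and
# sample sizes: 500 presences per side, 2000 background points)
dupSimFull <- function(seed = 11) {
  memoSim(paste0("dupfull", seed),
          vspConfig(nLayers = 4, coefs = c(3, -2, 0, 0),
                    noiseLayers = 3L,
                    duplicates = data.frame(layer = 4, source = 1,
                                            sd = 0.05),
                    seed = seed))
}

# hand-built 4-record table: 2 presences, 2 background
toySWD <- function() {
  SWD("toy",
      data.frame(X = c(0.5, 1.5, 2.5, 3.5), Y = c(0.5, 0.5, 1.5, 1.5)),
      c(1L, 1L, 0L, 0L),
      data.frame(temp = c(10, 12, 20, 25), prec = c(800, 650, 400, 300)),
      "background")
}

# randomized SWD for property tests
randomSWD <- function(n = 30, p = 3, seed = 1, withNA = FALSE) {
  set.seed(seed)
  dat <- as.data.frame(matrix(runif(n * p), n, p))
  colnames(dat) <- paste0("v", seq_len(p))
  if (withNA) dat[sample(n, 2), 1] <- NA
  SWD("rand", data.frame(X = runif(n), Y = runif(n)),
      rep(c(1L, 0L), length.out = n), dat, "background")
}

# brute-force AUC oracle: explicit double loop over all pairs
bruteAUC <- function(presence, contrast) {
  tot <- 0
  for (p in presence)
    for (c_ in contrast)
      tot <- tot + (p > c_) + 0.5 * (p == c_)
  tot / (length(presence) * length(contrast))
}

# exhaustive TSS oracle, independent of the implementation
bruteTSS <- function(presence, contrast) {
  best <- -Inf
  for (t in unique(c(presence, contrast))) {
    v <- mean(presence >= t) + mean(contrast < t) - 1
    if (v > best) best <- v
  }
  best
}
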