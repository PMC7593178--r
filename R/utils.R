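# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.  All stochastic operations in
# the package route through this so partitioning, sampling and training
# are pure functions of (inputs, seed).
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# round-half-down: 2.5 -> 2, 2.51 -> 3.  Used for hold-out test sizes so
# per-class counts are exactly predictable.
roundHalfDown <- function(x) ceiling(x - 0.5)

# per-step progress line; replaces interactive charts with
# machine-parseable logs.
logStep <- function(tag, ...) {
  if (!isTRUE(getOption("habtune.quiet", FALSE)))
    message(sprintf("[%s] %s", tag, paste0(..., collapse = "")))
}

isMissing <- function(x) is.null(x) || (length(x) == 1L && is.na(x))
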