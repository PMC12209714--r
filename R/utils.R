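# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and stream index, kept below 2^31.
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(stream)) %% 2147483647)
}

stopIf <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}

# Stratified fold indices: subjects of each stratum are shuffled and dealt
# round-robin into nFolds folds. Returns an integer fold id per subject.
stratifiedFolds <- function(strata, nFolds, seed) {
  fold <- integer(length(strata))
  withSeed(seed, {
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  fold
}
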