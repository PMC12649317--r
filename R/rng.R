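# Seed plumbing shared by the instance generator and the trial harness.

# Evaluate `code` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive `n` independent sub-seeds from a master seed. Kept below 2^31 so
# they are valid arguments to set.seed() on every platform.
derive_subseeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
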