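# RNG scoping: set a seed for a reproducible block, then restore whatever
# state the caller had so package functions do not perturb user RNG streams.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic replicate seed from (master_seed, size, replicate), kept
# inside 32-bit integer range, so any subset of the resampling design
# reproduces identically. Mixing constants are arbitrary primes; the
# contract is determinism and no collisions within one design.
derive_seed <- function(master_seed, size, replicate) {
  s <- (as.double(master_seed) %% 1e6) * 1009 +
    as.double(size) * 97003 + as.double(replicate) * 101
  as.integer(s %% 2147483647) + 1L
}
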