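# Seed scoping: run code under a fixed RNG seed without disturbing the
# caller's RNG state. All randomised operations in the package funnel
# through here so that seeded runs are exactly reproducible.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a parent seed and a stream index; keeps every
# consumer of randomness on its own reproducible stream below 2^31.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483629
}
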