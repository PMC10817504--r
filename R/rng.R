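# Seed plumbing. All simulation randomness flows through substream seeds
# derived from one master seed, so that adding a scene to a collection does
# not perturb any other scene, and the same config is bit-reproducible.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed from (master, year, day-of-year). Kept well
# below 2^31; multipliers are odd primes so nearby (year, doy) pairs do not
# collide within a run.
derive_seed <- function(master, year = 0L, doy = 0L, salt = 0L) {
  m <- as.double(master) %% 1e6
  s <- (m * 2017 + (as.double(year) %% 1000) * 104729 +
          as.double(doy) * 7919 + as.double(salt) * 15485863) %% 2147483629
  as.integer(s)
}
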