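# Seed handling: every stochastic entry point takes an explicit integer
# seed, sets the RNG locally, and restores the caller's RNG state on exit,
# so library code never clobbers the user's random stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a stream of child seeds from one parent seed (kept below 2^31).
child_seeds <- function(seed, n) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  sample.int(.Machine$integer.max - 1L, n)
}
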