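# evaluate expr under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# small deterministic seed derived from a base seed and a stream index,
# kept inside 32-bit integer range
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(stream) * 12347) %% 2147483647)
}
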