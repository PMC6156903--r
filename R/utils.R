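# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. A NULL seed uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# derive a reproducible sub-seed for an internal stage; stays within 32-bit
# integer range so it remains a valid set.seed() argument
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) + offset) %% .Machine$integer.max)
}
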