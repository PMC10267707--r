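# Evaluate code under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a root seed and a stream index; stays < 2^31
.childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(stream) * 12820163) %%
               2147483629)
}
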