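# internal helpers shared across modules

# Evaluate expr with the RNG seeded from `seed`, restoring the caller's
# RNG state afterwards: generators are bit-reproducible per seed without
# clobbering the session stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# linear interpolation of the crossing time of `level` between samples
# i and i+1 of (tt, v); assumes v[i] and v[i+1] bracket level
cross_time <- function(tt, v, i, level) {
  dv <- v[i + 1] - v[i]
  if (dv == 0) return(tt[i])
  tt[i] + (level - v[i]) / dv * (tt[i + 1] - tt[i])
}
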