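.datatable.aware <- TRUE

withSeed <- function(seed, expr) {
  # evaluate expr under a fixed RNG state without disturbing the caller's
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

bhAdjust <- function(p) p.adjust(p, method = "BH")
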