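# Shared internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All reproducibility contracts in the package
# go through this.
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

# Draw k reproducible sub-seeds from a master seed (31-bit, strictly positive).
derive_seeds <- function(master_seed, k) {
  with_seed(master_seed, sample.int(.Machine$integer.max, k, replace = FALSE))
}

# Content hash of an arbitrary R object (md5 of its version-2 serialization).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

stop_param <- function(...) stop(..., call. = FALSE)
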