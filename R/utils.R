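# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb the
# user's random stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic per-pair substream seed so surrogate results are independent
# of evaluation order. Kept below 2^31.
pair_seed <- function(master, i, j = 0L) {
  as.integer((as.numeric(master) + 99991 * as.numeric(i) + 101 * as.numeric(j)) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
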