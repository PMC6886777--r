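# Fast tibble constructor for hot paths: skips tibble()'s recycling and
# name-repair machinery. All columns must already have equal length.
new_tbl <- function(...) {
  lst <- list(...)
  tibble::new_tibble(lst, nrow = if (length(lst)) length(lst[[1]]) else 0L)
}

# Evaluate `expr` under a temporary RNG seeded with `seed`, restoring the
# caller's RNG state afterwards, so seeded components never perturb the
# global random stream.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
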