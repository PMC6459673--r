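# internal helpers

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Deterministic derived seed for subtask i of a run seeded with `seed`.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

match_side <- function(side) {
  match.arg(side, c("primary", "mirrored"))
}
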