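## Internal helpers: seeded RNG scoping and seed derivation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards, so no package function leaks global
# RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a stream of sub-seeds from a master seed. Results
# stay below 2^31 so they are valid R integer seeds.
derive_seed <- function(master, label, index = 0L) {
  stopifnot(length(master) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  s <- (as.double(master) * 48271 + h * 7919 + as.double(index) * 104729) %%
    2147483629
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
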