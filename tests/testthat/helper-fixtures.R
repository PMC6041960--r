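# Shared fixtures, built once per test run. Small scales keep the suite fast;
# the full desk-scale experiment lives in test-acceptance.R only.

# tiny lexicon for structural / scoring tests
tiny_lexicon <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_lexicon(n_chars = 30, n_words = 150,
                                 n_per_condition = 4, seed = 42,
                                 max_retries = 20)
    }
    cache
  }
})

# very small network spec matched to the tiny lexicon
tiny_spec <- function(lex = tiny_lexicon(), hidden = 8, n_timesteps = 20,
                      ...) {
  spec_for_lexicon(lex, hidden = hidden, n_timesteps = n_timesteps, ...)
}

# hand-coded step-by-step oracle for the settling dynamics: an independent
# implementation of s = b + W a ; x <- x + rate (s - x); a = 1/(1+exp(-g x)),
# operating on the same layer/connection description
oracle_forward <- function(net, task, input) {
  spec <- net$spec
  sizes <- spec$layers$size
  offs <- cumsum(c(0, sizes))
  total <- sum(sizes)
  task_def <- kanjinet:::TASKS[[task]]
  cl <- match(task_def$clamp, spec$layers$name)
  clamp_ix <- (offs[cl] + 1):offs[cl + 1]
  les_ix <- integer(0)
  if (!is.null(net$lesion)) {
    ll <- match(net$lesion$layer, spec$layers$name)
    les_ix <- offs[ll] + net$lesion$units
  }
  a <- rep(0.5, total)
  a[clamp_ix] <- input
  a[les_ix] <- 0
  A <- matrix(NA_real_, total, spec$n_timesteps + 1)
  A[, 1] <- a
  x <- rep(0, total)
  bias <- unlist(net$biases, use.names = FALSE)
  for (t in seq_len(spec$n_timesteps)) {
    s <- bias
    for (k in seq_len(nrow(spec$connections))) {
      fi <- match(spec$connections$from[k], spec$layers$name)
      ti <- match(spec$connections$to[k], spec$layers$name)
      f_ix <- (offs[fi] + 1):offs[fi + 1]
      t_ix <- (offs[ti] + 1):offs[ti + 1]
      s[t_ix] <- s[t_ix] + as.numeric(net$weights[[k]] %*% A[f_ix, t])
    }
    x <- x + spec$integration_rate * (s - x)
    a_new <- 1 / (1 + exp(-spec$gain * x))
    a_new[clamp_ix] <- input
    a_new[les_ix] <- 0
    A[, t + 1] <- a_new
  }
  A
}

# flatten a forward_pass() result (list of per-layer matrices) into the
# concatenated-unit matrix the oracle produces
flatten_traj <- function(traj) do.call(rbind, traj)
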