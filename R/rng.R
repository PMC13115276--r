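# Reproducibility helpers: the package never mutates the caller's RNG state,
# and training uses two independent streams (batch sampling, Gaussian noise)
# so that changing the batch geometry cannot perturb the noise draws.

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# A stream is an environment holding a saved .Random.seed.
rng_stream <- function(seed) {
  old <- get_rng_state()
  set.seed(seed)
  e <- new.env(parent = emptyenv())
  e$state <- get_rng_state()
  set_rng_state(old)
  e
}

# Evaluate fn() with the stream's RNG state active; update the stream and
# restore the caller's state afterwards.
with_stream <- function(stream, fn) {
  old <- get_rng_state()
  set_rng_state(stream$state)
  on.exit(set_rng_state(old), add = TRUE)
  res <- fn()
  stream$state <- get_rng_state()
  res
}

# Derive child seeds (< 2^31) deterministically from a run seed.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
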