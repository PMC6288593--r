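# Independent, resumable RNG streams.
#
# Training schedules interleave two tasks; to make a task's arithmetic
# independent of what the other task draws (and to make alternating and
# sequential schedules bit-identical when they should be), every stateful
# component owns a stream: a saved `.Random.seed` swapped in around its
# draws and swapped back out afterwards.

rng_stream <- function(seed) {
  s <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
  set.seed(seed)
  s$state <- get(".Random.seed", envir = .GlobalEnv)
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  s
}

with_stream <- function(stream, code) {
  if (!exists(".Random.seed", envir = .GlobalEnv)) stats::runif(1L)
  old <- get(".Random.seed", envir = .GlobalEnv)
  assign(".Random.seed", stream$state, envir = .GlobalEnv)
  on.exit({
    stream$state <- get(".Random.seed", envir = .GlobalEnv)
    assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  code
}

# Derive a child seed (< 2^31) from a base seed and a character tag.
derive_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}
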