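# Local RNG streams: every stochastic operation in the package draws from
# an explicit seeded stream and leaves the caller's .Random.seed untouched.

init_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(round(as.numeric(seed)) %% 2147483647))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  e
}

with_rng <- function(rng, fn) {
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}

runif_rng <- function(rng, n, min = 0, max = 1) {
  with_rng(rng, function() stats::runif(n, min, max))
}

rnorm_rng <- function(rng, n, mean = 0, sd = 1) {
  with_rng(rng, function() stats::rnorm(n, mean, sd))
}

sample_rng <- function(rng, n, k) {
  with_rng(rng, function() sample.int(n, k))
}
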