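# Seeded RNG streams that never touch the caller's .Random.seed.
# Every generator in the package takes a mandatory seed and is a pure
# function of (arguments, seed); reruns are bit-identical.

local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- new.env(parent = emptyenv())
  genv <- globalenv()
  swap_in <- function() {
    env$saved <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
      get(".Random.seed", envir = genv, inherits = FALSE) else NULL
    assign(".Random.seed", env$state, envir = genv)
  }
  swap_out <- function() {
    env$state <- get(".Random.seed", envir = genv, inherits = FALSE)
    if (is.null(env$saved)) {
      rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", env$saved, envir = genv)
    }
  }
  # initialize the private stream
  saved <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  env$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  if (is.null(saved)) rm(".Random.seed", envir = genv)
  else assign(".Random.seed", saved, envir = genv)

  draw <- function(fun) {
    function(...) {
      swap_in()
      on.exit(swap_out())
      fun(...)
    }
  }
  list(
    unif = draw(function(n, min = 0, max = 1) stats::runif(n, min, max)),
    norm = draw(function(n, mean = 0, sd = 1) stats::rnorm(n, mean, sd)),
    sample_int = draw(function(n, size, replace = FALSE, prob = NULL)
      sample.int(n, size, replace = replace, prob = prob)),
    # derive a child integer seed (kept below 2^31) for sub-generators
    child_seed = draw(function() sample.int(.Machine$integer.max - 1L, 1L))
  )
}
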