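# Internal helpers: condition classes and scoped RNG state.

abort_validation <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("matriline_validation_error",
                                          "matriline_error")))
}

abort_convergence <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("matriline_convergence_error",
                                          "matriline_error")))
}

abort_quantile <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("matriline_quantile_error",
                                          "matriline_error")))
}

# Seed the RNG for the calling scope and return a restorer, so that seeded
# package functions never perturb the caller's random stream.
local_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    abort_validation("'seed' must be a single integer")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    restore <- function() assign(".Random.seed", old, envir = globalenv())
  } else {
    restore <- function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  }
  set.seed(as.integer(seed))
  restore
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == trunc(x) && x >= 1
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
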