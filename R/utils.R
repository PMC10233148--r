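#' @keywords internal
"_PACKAGE"

## Internal RNG helpers: every stochastic operation takes an explicit seed and
## runs in a local RNG scope, so the caller's global .Random.seed is untouched
## and one master seed fans out to reproducible substreams.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic substream derivation (Lehmer-style mix, kept below 2^31).
child_seed <- function(master, index) {
  m <- 2147483647
  s <- (as.double(master) %% m) + 1
  x <- (s * 48271 + as.double(index) * 16807 + 12345) %% m
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("nirblup_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("nirblup_data_error", "error")))
}

stop_compute <- function(..., trace = NULL) {
  stop(errorCondition(paste0(...), trace = trace,
                      class = c("nirblup_compute_error", "error")))
}
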