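# Internal helpers shared across modules.

# Consistent error prefix so callers can grep logs for the failing stage.
stop_subloc <- function(msg, ..., class = "subloc_error") {
  rlang::abort(sprintf(msg, ...), class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_subloc("`%s` must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    stop_subloc("`%s` must be > %s (got %s)", name, lower, x)
  }
  if (x < lower || x > upper) {
    stop_subloc("`%s` must be in [%s, %s] (got %s)", name, lower, upper, x)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_subloc("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

# All generators take an integer seed and must be byte-reproducible.
# R's Mersenne-Twister state is set locally and restored on exit so that
# library code never perturbs the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_subloc("`seed` must be a single integer")
  }
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

`%||%` <- function(a, b) if (is.null(a)) b else a
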