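# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  expr
}

stop_petriage <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "petriage_error"), ...)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf, class = "petriage_parameter_error") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_petriage(
      sprintf("`%s` must be a single number in [%s, %s].", name, format(min), format(max)),
      class
    )
  }
  invisible(x)
}

# Round to the nearest value of a discrete score support (e.g. CDR half steps).
snap_to <- function(x, support) {
  support[max.col(-abs(outer(x, support, "-")), ties.method = "first")]
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
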