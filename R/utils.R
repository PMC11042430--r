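#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
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

# Derive a per-stage seed from a global one, staying inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2048L + as.integer(offset) %% 2048L
}

logistic <- function(x) 1 / (1 + exp(-x))

stop_with <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cfcdetect_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop_with("cfcdetect_nonfinite", "%s contains NaN/Inf values", what)
  }
  invisible(x)
}
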