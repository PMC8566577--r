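# Internal helpers shared across modules.

abort_value <- function(msg, ...) rlang::abort(msg, class = "fbcsp_value_error", ...)
abort_format <- function(msg, ...) rlang::abort(msg, class = "fbcsp_format_error", ...)
abort_io <- function(msg, ...) rlang::abort(msg, class = "fbcsp_io_error", ...)
abort_config <- function(msg, ...) rlang::abort(msg, class = "fbcsp_config_error", ...)

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stream sub-seed derivation, kept inside 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(i)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
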