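# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so generator functions are deterministic
#' in `seed` without leaking state into the caller's RNG stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
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
  expr
}

# derive a child seed from a run seed; kept below 2^31
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

assert_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_left) x > 0 else x >= 0) &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) stop(sprintf("`%s` must lie in [0,1]", name), call. = FALSE)
  invisible(as.numeric(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
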