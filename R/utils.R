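# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random number stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic seed splitting: derive stream k from a master seed.  Keeps
# results below 2^31 - 1 so they remain valid R integer seeds.
split_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + 7919 * as.numeric(k)) %%
               2147483647)
}

# assertion helper with caller-friendly message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}
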