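# Internal helpers shared across the package.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package internals do
#' not disturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  })
  set.seed(seed)
  expr
}

# k-fold assignment: seeded permutation, folds as equal as possible
fold_assignment <- function(n, k, seed) {
  if (k > n) stop("number of folds (", k, ") exceeds number of rows (", n, ")")
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# stopifnot with a readable message
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

# coerce AAStringSet / named character to named character, keeping names
as_named_chr <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  names(x) <- nm
  x
}
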