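## Internal helpers: scoped RNG and seed derivation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded draws inside the package do
#' not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a purpose-specific seed from one global seed
#'
#' A single run seed expands deterministically into independent seeds for
#' negative sampling, fold assignment, parameter initialization, etc., so
#' components stay individually reproducible inside a reproducible run.
#'
#' @param seed integer global seed.
#' @param purpose character tag naming the consumer.
#' @param index optional integer (e.g. round or fold number).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, purpose, index = 0L) {
  stopifnot(is.character(purpose), length(purpose) == 1L)
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  ## mix with multiplicative hashing, kept inside 31 bits
  x <- (as.double(seed) %% 2147483647) * 48271 + h * 69621 + as.double(index) * 16807
  as.integer(x %% 2147483647)
}

## stop() with a sprintf-style message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
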