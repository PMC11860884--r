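# Named per-stage seed substreams derived from one master seed, so toggling
# one stage never shifts another's randomness. Offsets are fixed; derived
# seeds stay below 2^31 - 1.
.streamOffsets <- c(
  cohort = 1L, sequence = 2L, expression = 3L, network = 4L,
  genesets = 5L, targets = 6L, walk = 7L, shuffle = 8L, misc = 9L)

#' Derive a named seed substream from a master seed
#'
#' @param seed master seed (integer).
#' @param stream one of the named stages in the pipeline.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @keywords internal
deriveSeed <- function(seed, stream = "misc") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  off <- .streamOffsets[[match.arg(stream, names(.streamOffsets))]]
  as.integer((abs(as.numeric(seed)) + 97561 * off) %% 2147483647)
}

# Normalize gene symbols: trim whitespace, upper-case, drop empties.
.normSymbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

# Run expr under a fixed seed without disturbing the caller's RNG state;
# NULL seed means use the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(seed, expr)
}

.assertProb <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  invisible(x)
}

.assertCount <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x))
    stop(what, " must be an integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

#' @importFrom stats setNames
#' @importFrom utils head
NULL
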