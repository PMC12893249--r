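#' @keywords internal
"_PACKAGE"

## Condition helper: all package errors carry a subclass so callers and tests
## can distinguish configuration errors from data errors.
sl_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "spikeloop_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so that seeded package internals
#' never disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a parent seed
#'
#' Deterministic splitting of one user-facing seed into independent
#' per-component streams. All randomness in the package flows from an
#' explicit seed through this function; no global RNG state is relied upon.
#'
#' @param seed Parent integer seed.
#' @param ... Integers and/or strings naming the stream (hashed together).
#' @return An integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.character(as.integer(seed)), vapply(list(...), as.character, ""))
  h <- 0
  for (ch in utf8ToInt(paste(parts, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

## round-half-up at a given number of decimals (presentation rounding for
## printed-table comparison; R's round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)
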