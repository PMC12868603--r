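#' @keywords internal
"_PACKAGE"

# Calendar-to-survival time conversion. Horizons are quoted in months but
# records carry dates; one month is defined as 30.4375 days throughout.
DAYS_PER_MONTH <- 30.4375

#' Months elapsed between two dates
#'
#' Converts a date difference to months using a fixed 30.4375 days/month.
#'
#' @param from,to `Date` vectors.
#' @return Numeric vector of (possibly fractional) months.
#' @export
months_between <- function(from, to) {
  as.numeric(as.Date(to) - as.Date(from)) / DAYS_PER_MONTH
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Derive a child seed from a base seed and a stream label
#'
#' Gives each randomised pipeline stage (splitting, training, imputation, ...)
#' its own reproducible stream while staying within 32-bit integer range.
#'
#' @param seed Base integer seed.
#' @param stream Character label of the stream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483563) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
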