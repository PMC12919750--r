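# Shared internal helpers: rounding, apportionment, input checking.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages in nutrition
#' and usability tables conventionally round half up, and the package's metric
#' tables depend on that convention (e.g. 0.85 -> 85.1 at one decimal when the
#' exact ratio is 74/87).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Largest-remainder apportionment of an integer total
#'
#' Splits `n` into integer counts proportional to `weights` using the
#' Hamilton / largest-remainder method: floor the quotas, then hand the
#' remaining units to the largest fractional remainders (ties broken by
#' position, first wins).
#'
#' @param n positive integer total.
#' @param weights non-negative weights; need not sum to one.
#' @return integer vector of counts summing exactly to `n`.
#' @keywords internal
largest_remainder <- function(n, weights) {
  stopifnot(n >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- n * weights / sum(weights)
  counts <- floor(quota + sqrt(.Machine$double.eps))
  left <- n - sum(counts)
  if (left > 0) {
    rem <- quota - counts
    # order by remainder descending, ties by index ascending
    idx <- order(-rem, seq_along(rem))[seq_len(left)]
    counts[idx] <- counts[idx] + 1
  }
  as.integer(counts)
}

# stop() with call.=FALSE everywhere; small wrapper keeps messages uniform
fail <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @keywords internal
match_enum <- function(x, choices, what) {
  if (!is_string(x) || !(x %in% choices)) {
    fail(sprintf("invalid %s: '%s' (allowed: %s)", what,
                 paste(x, collapse = ","), paste(choices, collapse = ", ")))
  }
  x
}

# Local RNG scope: run expr with a temporary seed, restoring the caller's
# random state afterwards so package functions do not clobber user streams.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
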