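#' Counting-window durations
#'
#' `log_spaced_bin_sizes()` returns `n` durations spaced geometrically between
#' `min_ms` and `max_ms` (endpoints exact); the defaults give the ten windows,
#' 100 ms to 1 s, used for the correlation analyses. `linear_spaced_bin_sizes()`
#' returns equally spaced durations; the defaults give the five windows,
#' 200 ms to 1 s, used for the single-unit count statistics.
#'
#' @param min_ms,max_ms Smallest and largest duration, ms; `0 < min < max`.
#' @param n Number of durations, at least 2.
#' @return Numeric vector of durations in ms.
#' @examples
#' log_spaced_bin_sizes()
#' linear_spaced_bin_sizes()
#' @export
log_spaced_bin_sizes <- function(min_ms = 100, max_ms = 1000, n = 10) {
  check_bin_bounds(min_ms, max_ms, n)
  out <- exp(seq(log(min_ms), log(max_ms), length.out = n))
  out[1] <- min_ms
  out[n] <- max_ms
  out
}

#' @rdname log_spaced_bin_sizes
#' @export
linear_spaced_bin_sizes <- function(min_ms = 200, max_ms = 1000, n = 5) {
  check_bin_bounds(min_ms, max_ms, n)
  seq(min_ms, max_ms, length.out = n)
}

check_bin_bounds <- function(min_ms, max_ms, n) {
  if (!(is.numeric(min_ms) && is.numeric(max_ms) && min_ms > 0 && min_ms < max_ms)) {
    rlang::abort("need 0 < min_ms < max_ms")
  }
  if (n < 2) rlang::abort("need at least 2 bin sizes")
  invisible(TRUE)
}
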