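# smallest integer j with m^j >= n, i.e. ceiling(log(n, m)).  Repeated
# ceiling division keeps every intermediate below 2^53, so the result is
# exact (no floating-point drift at n = m^j) for any n up to (5e7)^2.
ceil_log_int <- function(n, m) {
  j <- 0L
  while (n > 1) {
    n <- (n + m - 1) %/% m
    j <- j + 1L
  }
  j
}

#' Logarithmic reference bounds for a string length
#'
#' For a string of length `n` over `m` symbols, the log length is
#' `LG = log(n, m)` and the double log length is `2LG = 2 * log(n, m)`.
#' Their ceilings are the reference values of the log-bounds test: in a
#' random string the shortest hapax is expected at or below `ceiling(LG)`
#' and the longest repeat to satisfy `mrl + 1 = ceiling(2LG)`.  Ceilings
#' are computed by exact integer comparison, so `n = m^j` gives
#' `ceiling(LG) = j` without drift.
#'
#' @param n String length, `n >= 1`.
#' @param m Alphabet size, `m >= 2`.
#' @return An object of class `log_bounds`: `n`, `m`, `lg`, `two_lg`,
#'   `ceil_lg`, `ceil_two_lg`.
#' @examples
#' b <- log_bounds(100000, 10)
#' c(b$ceil_lg, b$ceil_two_lg)  # 5 10
#' @export
log_bounds <- function(n, m) {
  n <- as.numeric(n)
  m <- as.numeric(m)
  if (m < 2) stop("degenerate alphabet")
  if (n < 1) stop("n must be >= 1")
  structure(
    list(
      n = n, m = m,
      lg = log(n) / log(m),
      two_lg = 2 * log(n) / log(m),
      ceil_lg = ceil_log_int(n, m),
      ceil_two_lg = ceil_log_int(n * n, m)  # ceiling(2 log_m n), exact
    ),
    class = "log_bounds"
  )
}

#' @export
print.log_bounds <- function(x, ...) {
  cat(sprintf(
    "<log_bounds> n = %s, m = %d: LG = %.4f (ceil %d), 2LG = %.4f (ceil %d)\n",
    format(x$n, big.mark = ","), x$m, x$lg, x$ceil_lg, x$two_lg,
    x$ceil_two_lg))
  invisible(x)
}

#' Predicted hapax floor for a random string
#'
#' `ceiling(2 * log(n, m))`: at and above this word length every k-mer of a
#' random string is expected to be a hapax; equivalently, a random string
#' should have `mrl + 1` equal to this value.
#'
#' @inheritParams log_bounds
#' @return Integer.
#' @export
predicted_hapax_floor <- function(n, m) log_bounds(n, m)$ceil_two_lg

#' Predicted repeat ceiling for a random string
#'
#' `ceiling(log(n, m))`: the expected upper bound for the shortest hapax
#' (`mhl`) of a random string.
#'
#' @inheritParams log_bounds
#' @return Integer.
#' @export
predicted_repeat_ceiling <- function(n, m) log_bounds(n, m)$ceil_lg

#' Score one prefix against the logarithmic bounds
#'
#' Applies the coincidence rule of the log-bounds test: a prefix passes the
#' hapax check when `|mhl - ceiling(LG)| <= 1` and the repeat check when
#' `|mrl + 1 - ceiling(2LG)| <= 1`.  Deviations are recorded signed.
#'
#' @param mhl Minimum hapax length of the prefix.
#' @param mrl Maximum repeat length of the prefix.
#' @param bounds A [log_bounds()] for the same prefix length and alphabet.
#' @return A one-row data frame: `n`, `mhl`, `ceil_lg`, `mhl_check`,
#'   `mrl_plus1`, `ceil_two_lg`, `mrl_check`, `dev_mhl`, `dev_mrl`.
#' @examples
#' check_row(4, 9, log_bounds(1e5, 10))  # both checks pass
#' @export
check_row <- function(mhl, mrl, bounds) {
  stopifnot(inherits(bounds, "log_bounds"))
  dev_mhl <- mhl - bounds$ceil_lg
  dev_mrl <- (mrl + 1) - bounds$ceil_two_lg
  data.frame(
    n = bounds$n,
    mhl = mhl,
    ceil_lg = bounds$ceil_lg,
    mhl_check = abs(dev_mhl) <= 1,
    mrl_plus1 = mrl + 1,
    ceil_two_lg = bounds$ceil_two_lg,
    mrl_check = abs(dev_mrl) <= 1,
    dev_mhl = dev_mhl,
    dev_mrl = dev_mrl
  )
}

#' Default prefix schedule
#'
#' Decade and half-decade checkpoints `{10^j, 2*10^j, 5*10^j}` intersected
#' with `[10, n]`, plus `n` itself.
#'
#' @param n Full string length.
#' @return Sorted integer vector of prefix lengths.
#' @export
default_prefixes <- function(n) {
  if (n < 10) return(n)
  j <- 1:floor(log10(n))
  vals <- sort(unique(c(outer(c(1, 2, 5), 10^j), n)))
  vals[vals >= 10 & vals <= n]
}
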