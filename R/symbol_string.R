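#' Encode a sequence of symbols for index computation
#'
#' Turns a character string (or a vector of single-symbol tokens, or a
#' vector of non-negative integer codes) into a `symbol_string`: an
#' integer-coded sequence together with its alphabet.  All index and test
#' functions in the package operate on this representation.
#'
#' When `alphabet` is `NULL` the alphabet is inferred from the data and
#' codes are assigned in order of first appearance.  When `alphabet` is
#' given, codes follow its order and any symbol outside it is an error.
#' The declared alphabet size `m` may exceed the number of distinct symbols
#' actually present (e.g. a short DNA fragment declared over the 4-letter
#' nucleotide alphabet); `m` is the base of every logarithm in the package
#' and the base of the `m^k` completeness counts.
#'
#' @param x A length-1 character string (split into single characters), a
#'   character vector of single-symbol tokens, or a vector of non-negative
#'   integer codes.
#' @param alphabet Optional character vector fixing the symbol order, or
#'   (when `x` is integer) ignored in favour of `m`.
#' @param m Optional declared alphabet size; must be at least the number of
#'   distinct symbols present.  Defaults to the inferred/declared alphabet
#'   size.
#' @return An object of class `symbol_string` with fields `codes`
#'   (0-based integer codes), `alphabet` (character vector, may contain
#'   `NA` for codes never named), `n` (length) and `m` (alphabet size).
#' @examples
#' s <- symbol_string("banana")
#' s$n  # 6
#' s$m  # 3
#' symbol_string("acgt", alphabet = c("a", "c", "g", "t"))$m  # 4
#' @export
symbol_string <- function(x, alphabet = NULL, m = NULL) {
  if (inherits(x, "symbol_string")) return(x)
  if (is.numeric(x)) {
    codes <- as.integer(x)
    if (length(codes) == 0L) stop("empty sequence")
    if (anyNA(codes) || any(codes < 0L)) {
      stop("integer codes must be non-negative")
    }
    m_obs <- max(codes) + 1L
    if (is.null(m)) m <- m_obs
    if (m < m_obs) stop("alphabet violation: code outside declared alphabet")
    alph <- if (!is.null(alphabet)) as.character(alphabet) else
      as.character(seq_len(m) - 1L)
    if (length(alph) < m) alph <- c(alph, rep(NA_character_, m - length(alph)))
    return(new_symbol_string(codes, alph[seq_len(m)], as.integer(m)))
  }
  x <- as.character(x)
  if (length(x) == 1L) x <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (length(x) == 0L) stop("empty sequence")
  if (is.null(alphabet)) {
    alph <- unique(x)
  } else {
    alph <- as.character(alphabet)
    bad <- !(x %in% alph)
    if (any(bad)) {
      stop(sprintf("alphabet violation: symbol '%s' outside declared alphabet",
                   x[which(bad)[1L]]))
    }
  }
  codes <- match(x, alph) - 1L
  m_obs <- length(alph)
  if (is.null(m)) m <- m_obs
  if (m < m_obs) stop("declared m smaller than alphabet")
  alph <- c(alph, rep(NA_character_, m - m_obs))
  new_symbol_string(codes, alph, as.integer(m))
}

new_symbol_string <- function(codes, alphabet, m) {
  structure(
    list(codes = codes, alphabet = alphabet, n = length(codes), m = m),
    class = "symbol_string"
  )
}

#' @export
print.symbol_string <- function(x, ...) {
  cat(sprintf("<symbol_string> n = %d, m = %d\n", x$n, x$m))
  shown <- min(x$n, 60L)
  syms <- x$alphabet[x$codes[seq_len(shown)] + 1L]
  syms[is.na(syms)] <- "?"
  cat("  ", paste0(syms, collapse = ""),
      if (x$n > shown) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
format.symbol_string <- function(x, ...) {
  syms <- x$alphabet[x$codes + 1L]
  syms[is.na(syms)] <- "?"
  paste0(syms, collapse = "")
}

#' Extract a prefix of a symbol string
#'
#' @param x A `symbol_string`.
#' @param n Prefix length, `1 <= n <= x$n`.
#' @return A `symbol_string` over the same alphabet.
#' @export
prefix <- function(x, n) {
  x <- symbol_string(x)
  n <- as.integer(n)
  if (n < 1L || n > x$n) stop("prefix exceeds string")
  new_symbol_string(x$codes[seq_len(n)], x$alphabet, x$m)
}
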