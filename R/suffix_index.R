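#' Build a suffix index for a symbol string
#'
#' Constructs the suffix array (SA-IS, linear time) and the LCP array
#' (Kasai's algorithm) of a [symbol_string()].  All informational indexes
#' and multiplicity queries are answered from this structure; its output is
#' exact and is verified against naive suffix comparison in the test suite.
#'
#' @param x A `symbol_string` or anything [symbol_string()] accepts.
#' @param ... Passed to [symbol_string()] when `x` needs encoding.
#' @return An object of class `suffix_index`: the source string plus
#'   `sa` (1-based suffix start positions in lexicographic suffix order)
#'   and `lcp` (`lcp[i]` = longest common prefix of the suffixes at
#'   `sa[i-1]` and `sa[i]`; `lcp[1] = 0`).
#' @examples
#' idx <- suffix_index("banana")
#' idx$sa   # 6 4 2 1 5 3 : a, ana, anana, banana, na, nana
#' @export
suffix_index <- function(x, ...) {
  if (inherits(x, "suffix_index")) return(x)
  s <- symbol_string(x, ...)
  res <- cpp_suffix_index(s$codes, s$m)
  structure(
    list(string = s, sa = res$sa + 1L, lcp = res$lcp, n = s$n, m = s$m),
    class = "suffix_index"
  )
}

#' @export
print.suffix_index <- function(x, ...) {
  cat(sprintf("<suffix_index> n = %d, m = %d, max LCP = %d\n",
              x$n, x$m, max(x$lcp)))
  invisible(x)
}

#' Substring multiplicity
#'
#' Counts the occurrences of `word` in the indexed string.  Occurrences may
#' overlap: in `"aaaaa"` the word `"aa"` has multiplicity 4.
#'
#' @param x A `suffix_index` (or anything coercible via [suffix_index()]).
#' @param word The query: a character string over the same alphabet, or an
#'   integer code vector.
#' @return Integer count (0 when absent; symbols outside the alphabet give
#'   count 0).
#' @examples
#' multiplicity(suffix_index("banana"), "ana")  # 2
#' @export
multiplicity <- function(x, word) {
  x <- suffix_index(x)
  if (is.numeric(word)) {
    w <- as.integer(word)
  } else {
    word <- as.character(word)
    if (length(word) == 1L) word <- strsplit(word, "", fixed = TRUE)[[1L]]
    w <- match(word, x$string$alphabet) - 1L
    if (anyNA(w)) return(0L)
  }
  if (length(w) == 0L) stop("empty query")
  if (length(w) > x$n) return(0L)
  cpp_sa_multiplicity(x$string$codes, x$sa - 1L, w)
}
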