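#' Maximum repeat length
#'
#' Length of the longest substring occurring more than once (occurrences
#' may overlap).  Equals the maximum adjacent LCP in the suffix order.
#' A string with no repeated substring (all symbols distinct) has `mrl = 0`.
#'
#' @param x A `suffix_index` or anything coercible via [suffix_index()].
#' @return Integer, `0 <= mrl < n`.
#' @examples
#' max_repeat_length(suffix_index("banana"))  # 3 ("ana")
#' max_repeat_length(suffix_index("abcd"))    # 0
#' @export
max_repeat_length <- function(x) {
  x <- suffix_index(x)
  max(x$lcp, 0L)
}

#' Minimum hapax length
#'
#' Length of the shortest substring occurring exactly once (a hapax).
#' Always defined, since the whole string occurs once: `1 <= mhl <= n`.
#' The shortest unique substring starting at position `p` extends one
#' symbol past the longer of the LCPs with the two suffix-order neighbours
#' of the suffix at `p`, provided it fits before the string end; `mhl` is
#' the minimum over positions.
#'
#' @inheritParams max_repeat_length
#' @return Integer in `[1, n]`.
#' @examples
#' min_hapax_length(suffix_index("banana"))  # 1 ("b")
#' min_hapax_length(suffix_index("aabb"))    # 2 ("aa")
#' @export
min_hapax_length <- function(x) {
  x <- suffix_index(x)
  n <- x$n
  lcp_prev <- x$lcp
  lcp_next <- c(x$lcp[-1L], 0L)
  h <- pmax(lcp_prev, lcp_next) + 1L
  suf_len <- n - x$sa + 1L
  ok <- h <= suf_len
  min(h[ok])
}

#' Maximum complete length
#'
#' The largest `k` such that all `m^k` possible k-mers occur in the string,
#' with `m` the declared alphabet size.  Returns 0 when some declared
#' symbol never occurs.  The search stops at `ceiling(log(n, m))`, an upper
#' bound for `mcl`.
#'
#' @inheritParams max_repeat_length
#' @return Integer, `0 <= mcl <= ceiling(log(n, m))`.
#' @examples
#' max_complete_length(suffix_index("banana"))  # 1
#' max_complete_length(suffix_index(symbol_string("aab", m = 3)))  # 0
#' @export
max_complete_length <- function(x) {
  x <- suffix_index(x)
  if (x$m < 2L) {
    # unary alphabet: every k-mer (there is one) occurs for all k <= n
    return(x$n)
  }
  kmax <- ceil_log_int(x$n, x$m)
  mcl <- 0L
  for (k in seq_len(kmax)) {
    if (distinct_kmers(x, k) == x$m^k) mcl <- k else break
  }
  mcl
}

# |D_k|: number of distinct k-mers, from the LCP array.  A suffix shorter
# than k contributes no k-mer; an adjacent LCP >= k merges two k-mers
# (and implies both suffixes have length >= k).
distinct_kmers <- function(x, k) {
  (x$n - k + 1L) - sum(x$lcp >= k)
}

# multiplicities of the distinct k-mers, in suffix order: group suffixes of
# length >= k at breaks where the adjacent LCP drops below k
kmer_multiplicities <- function(x, k) {
  keep <- (x$n - x$sa + 1L) >= k
  l <- x$lcp[keep]
  tabulate(cumsum(l < k))
}

#' Per-k substring statistics
#'
#' Counts of distinct, hapax (multiplicity 1) and repeat (multiplicity > 1)
#' k-mers, together with the empirical k-entropy: the Shannon entropy, with
#' base-`m` logarithm, of the distribution `p(w) = mult(w) / (n - k + 1)`
#' over the distinct k-mers.
#'
#' @inheritParams max_repeat_length
#' @param k Word length, `1 <= k <= n`.
#' @return A list of class `kmer_stats`: `k`, `distinct`, `hapax`,
#'   `repeats`, `entropy`, `complete` (`TRUE` iff all `m^k` k-mers occur).
#' @examples
#' kmer_stats(suffix_index("abab"), 1)$entropy  # 1 (uniform over 2 symbols)
#' kmer_stats(suffix_index("aaaa"), 1)$entropy  # 0
#' @export
kmer_stats <- function(x, k) {
  x <- suffix_index(x)
  k <- as.integer(k)
  if (k < 1L || k > x$n) stop("invalid k")
  mult <- kmer_multiplicities(x, k)
  p <- mult / (x$n - k + 1L)
  ent_nat <- -sum(p * log(p))
  # a single-support distribution has zero entropy in every base; only a
  # positive entropy needs the base-m logarithm, which requires m >= 2
  entropy <- if (ent_nat == 0) 0 else if (x$m < 2L) {
    stop("degenerate alphabet: entropy needs m >= 2")
  } else {
    ent_nat / log(x$m)
  }
  structure(
    list(
      k = k,
      distinct = length(mult),
      hapax = sum(mult == 1L),
      repeats = sum(mult > 1L),
      entropy = entropy,
      complete = x$m >= 2L && length(mult) == x$m^k
    ),
    class = "kmer_stats"
  )
}

#' @export
print.kmer_stats <- function(x, ...) {
  cat(sprintf(
    "<kmer_stats> k = %d: distinct = %d (hapax %d, repeat %d), E_k = %.6f%s\n",
    x$k, x$distinct, x$hapax, x$repeats, x$entropy,
    if (x$complete) ", complete" else ""))
  invisible(x)
}

#' Informational index profile of a string
#'
#' One suffix-index construction, then all informational indexes: `mrl`,
#' `mhl`, `mcl` and per-k statistics ([kmer_stats()]) for the requested
#' word lengths.
#'
#' @param x A `symbol_string`, `suffix_index`, or raw input for
#'   [symbol_string()].
#' @param k Integer vector of word lengths for the per-k table; default
#'   `1:(mrl + 1)`.
#' @param m Optional declared alphabet size (used only when `x` still
#'   needs encoding).
#' @return An object of class `index_profile` with fields `mrl`, `mhl`,
#'   `mcl`, `n`, `m` and `per_k` (a data frame with one row per `k`).
#' @examples
#' p <- index_profile("banana")
#' c(p$mrl, p$mhl, p$mcl)  # 3 1 1
#' @export
index_profile <- function(x, k = NULL, m = NULL) {
  idx <- if (inherits(x, "suffix_index")) x else
    suffix_index(symbol_string(x, m = m))
  mrl <- max_repeat_length(idx)
  mhl <- min_hapax_length(idx)
  mcl <- max_complete_length(idx)
  if (is.null(k)) k <- seq_len(min(mrl + 1L, idx$n))
  per_k <- do.call(rbind, lapply(k, function(kk) {
    st <- kmer_stats(idx, kk)
    data.frame(k = st$k, distinct = st$distinct, hapax = st$hapax,
               repeats = st$repeats, entropy = st$entropy,
               complete = st$complete)
  }))
  structure(
    list(mrl = mrl, mhl = mhl, mcl = mcl, n = idx$n, m = idx$m,
         per_k = per_k),
    class = "index_profile"
  )
}

#' @export
print.index_profile <- function(x, ...) {
  cat(sprintf("<index_profile> n = %d, m = %d\n", x$n, x$m))
  cat(sprintf("  mrl = %d   mhl = %d   mcl = %d\n", x$mrl, x$mhl, x$mcl))
  if (!is.null(x$per_k) && nrow(x$per_k) > 0L) {
    print(x$per_k, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.index_profile <- function(x, ...) x$per_k

# JSON record with the stable field names mrl, mhl, mcl, per_k
#' Serialize an index profile to JSON
#'
#' @param x An `index_profile`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
profile_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "index_profile"))
  obj <- list(n = x$n, m = x$m, mrl = x$mrl, mhl = x$mhl, mcl = x$mcl,
              per_k = x$per_k)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
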