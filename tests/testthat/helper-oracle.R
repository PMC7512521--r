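# Naive reference implementations by direct enumeration of all substrings.
# Deliberately independent of the suffix-array code path: everything here
# works on plain character strings via substring().

# map a symbol_string to a character string whose character order equals
# the code order (so naive lexicographic sorting matches code sorting)
code_chars <- function(s) {
  stopifnot(s$m <= 26)
  intToUtf8(utf8ToInt("a") + s$codes, multiple = TRUE)
}

code_string <- function(s) paste(code_chars(s), collapse = "")

naive_kmer_counts <- function(str, k) {
  n <- nchar(str)
  stopifnot(k >= 1, k <= n)
  table(substring(str, 1:(n - k + 1), k:n))
}

naive_mrl <- function(str) {
  n <- nchar(str)
  mrl <- 0L
  for (k in seq_len(n - 1)) {
    if (any(naive_kmer_counts(str, k) > 1)) mrl <- k else break
  }
  mrl
}

naive_mhl <- function(str) {
  n <- nchar(str)
  for (k in seq_len(n)) {
    if (any(naive_kmer_counts(str, k) == 1)) return(k)
  }
  stop("unreachable: the whole string is a hapax")
}

naive_mcl <- function(str, m) {
  n <- nchar(str)
  mcl <- 0L
  for (k in seq_len(n)) {
    if (length(naive_kmer_counts(str, k)) == m^k) mcl <- k else break
  }
  mcl
}

naive_entropy <- function(str, k, m) {
  counts <- as.integer(naive_kmer_counts(str, k))
  p <- counts / (nchar(str) - k + 1)
  e <- -sum(p * log(p))
  if (e == 0) 0 else e / log(m)
}

naive_multiplicity <- function(str, word) {
  n <- nchar(str)
  k <- nchar(word)
  if (k > n) return(0L)
  sum(substring(str, 1:(n - k + 1), k:n) == word)
}

naive_suffix_order <- function(str) {
  n <- nchar(str)
  order(substring(str, 1:n, n))
}

naive_lcp_pair <- function(a, b) {
  k <- 0L
  while (k < nchar(a) && k < nchar(b) &&
         substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1)) {
    k <- k + 1L
  }
  k
}

# random symbol_string over m symbols, full declared alphabet
random_string <- function(n, m) {
  uniform_string(n, m)
}
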