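test_that("mrl, mhl, mcl match brute force on the worked examples", {
  expect_equal(max_repeat_length(suffix_index("banana")), 3L)  # "ana"
  expect_equal(max_repeat_length(suffix_index("abcd")), 0L)
  expect_equal(min_hapax_length(suffix_index("banana")), 1L)   # "b"
  expect_equal(min_hapax_length(suffix_index("aabb")), 2L)     # "aa"
  expect_equal(max_complete_length(suffix_index("banana")), 1L)
  expect_equal(max_complete_length(suffix_index("abcd")), 1L)
  # declared symbol never occurs -> incomplete at k = 1
  expect_equal(max_complete_length(suffix_index(symbol_string("aab", m = 3))),
               0L)

  p <- index_profile("banana")
  expect_equal(c(p$mrl, p$mhl, p$mcl), c(3L, 1L, 1L))
  p2 <- index_profile("abcd")
  expect_equal(c(p2$mrl, p2$mhl, p2$mcl), c(0L, 1L, 1L))
})

test_that("kmer_stats matches the entropy formula on known cases", {
  st <- kmer_stats(suffix_index("aaaa"), 1)
  expect_equal(st$distinct, 1L)
  expect_equal(st$entropy, 0)

  st <- kmer_stats(suffix_index("abab"), 1)   # p(a) = p(b) = 1/2, base 2
  expect_equal(st$entropy, 1)
  expect_true(st$complete)

  # all k-mers hapax -> entropy at the uniform maximum log_m(n - k + 1)
  s <- symbol_string("abcdefghij")
  st <- kmer_stats(suffix_index(s), 2)
  expect_equal(st$hapax, st$distinct)
  expect_equal(st$entropy, log(s$n - 2 + 1) / log(s$m))

  expect_error(kmer_stats(suffix_index("abc"), 0), "invalid k")
  expect_error(kmer_stats(suffix_index("abc"), 4), "invalid k")
})

test_that("suffix-structure indexes equal naive enumeration on random strings", {
  set.seed(101)
  for (m in c(2, 4, 10, 26)) {
    for (rep in 1:6) {
      n <- sample(5:500, 1)
      s <- random_string(n, m)
      idx <- suffix_index(s)
      str <- code_string(s)
      expect_equal(max_repeat_length(idx), naive_mrl(str))
      expect_equal(min_hapax_length(idx), naive_mhl(str))
      expect_equal(max_complete_length(idx), naive_mcl(str, s$m))
      for (k in unique(pmin(c(1, 2, 3, 5), n))) {
        st <- kmer_stats(idx, k)
        counts <- naive_kmer_counts(str, k)
        expect_equal(st$distinct, length(counts))
        expect_equal(st$hapax, sum(counts == 1))
        expect_equal(st$repeats, sum(counts > 1))
        expect_equal(st$entropy, naive_entropy(str, k, s$m),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("repeat/hapax propositions hold on generated strings", {
  set.seed(202)
  strings <- c(
    list(symbol_string("banana"), symbol_string("mississippi")),
    lapply(1:8, function(i) random_string(sample(10:300, 1),
                                          sample(c(2, 4, 10), 1)))
  )
  for (s in strings) {
    idx <- suffix_index(s)
    mrl <- max_repeat_length(idx)
    mhl <- min_hapax_length(idx)
    mcl <- max_complete_length(idx)
    n <- s$n

    # beyond mrl every k-mer is a hapax
    for (k in (mrl + 1):min(mrl + 3, n)) {
      st <- kmer_stats(idx, k)
      expect_equal(st$repeats, 0L)
      expect_equal(st$hapax, st$distinct)
    }
    # below mhl every k-mer is a repeat
    if (mhl > 1) {
      for (k in 1:(mhl - 1)) {
        expect_equal(kmer_stats(idx, k)$hapax, 0L)
      }
    }
    # ordering and cardinality bounds
    expect_gte(mhl, mcl)
    expect_lte(mcl, ceiling(log(n) / log(s$m)) + 1e-9)
    expect_gte(mrl, 0L); expect_lt(mrl, n)
    expect_gte(mhl, 1L); expect_lte(mhl, n)
    for (k in unique(pmin(c(1, 3, mrl + 1), n))) {
      st <- kmer_stats(idx, k)
      expect_lte(st$distinct, n - k + 1)
      expect_lte(st$distinct, s$m^k)
      if (st$distinct == n - k + 1) {
        expect_equal(st$hapax, st$distinct)
        expect_equal(st$entropy, log(n - k + 1) / log(s$m),
                     tolerance = 1e-9)
      }
      expect_equal(st$distinct, st$hapax + st$repeats)
    }
  }
})

test_that("substrings of repeats are repeats; superstrings of hapaxes are hapaxes", {
  set.seed(303)
  s <- random_string(200, 4)
  idx <- suffix_index(s)
  n <- s$n
  for (rep in 1:30) {
    k <- sample(2:10, 1)
    i <- sample(1:(n - k + 1), 1)
    word <- s$codes[i:(i + k - 1)]
    if (multiplicity(idx, word) > 1) {
      # every proper substring of a repeat is a repeat
      expect_gt(multiplicity(idx, word[-1]), 1)
      expect_gt(multiplicity(idx, word[-k]), 1)
    }
    if (multiplicity(idx, word) == 1 && i + k <= n) {
      # extending a hapax inside the string keeps it a hapax
      expect_equal(multiplicity(idx, s$codes[i:(i + k)]), 1L)
    }
  }
})

test_that("index profile serializes to JSON with stable field names", {
  p <- index_profile("banana")
  js <- jsonlite::fromJSON(profile_json(p))
  expect_equal(js$mrl, 3L)
  expect_equal(js$mhl, 1L)
  expect_equal(js$mcl, 1L)
  expect_equal(names(js$per_k),
               c("k", "distinct", "hapax", "repeats", "entropy", "complete"))
})
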