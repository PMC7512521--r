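test_that("logarithmic bounds and ceilings are exact", {
  b <- log_bounds(100000, 10)
  expect_equal(b$ceil_lg, 5L)
  expect_equal(b$ceil_two_lg, 10L)

  b <- log_bounds(100, 10)
  expect_equal(b$ceil_lg, 2L)      # exact power: no off-by-one
  expect_equal(b$ceil_two_lg, 4L)

  b <- log_bounds(16, 2)
  expect_equal(b$ceil_lg, 4L)
  expect_equal(b$ceil_two_lg, 8L)

  expect_equal(b$two_lg, 2 * b$lg)
  expect_error(log_bounds(10, 1), "degenerate alphabet")

  # integer powers across bases, no floating drift
  for (m in c(2, 4, 10, 26, 256)) {
    for (j in 1:6) {
      expect_equal(log_bounds(m^j, m)$ceil_lg, j)
      expect_equal(log_bounds(m^j + 1, m)$ceil_lg, j + 1L)
    }
  }
})

test_that("predicted bounds reproduce table reference values", {
  expect_equal(predicted_hapax_floor(1e6, 10), 12L)
  expect_equal(predicted_hapax_floor(5e7, 10), 16L)
  expect_equal(predicted_hapax_floor(2^8, 2), 16L)     # n = m^8
  expect_equal(predicted_repeat_ceiling(1e7, 10), 7L)
  expect_equal(predicted_repeat_ceiling(10^3, 10), 3L) # n = m^3
  expect_equal(predicted_repeat_ceiling(5e7, 256), 4L)
})

test_that("the coincidence rule is a symmetric +/-1 tolerance", {
  b5 <- log_bounds(1e5, 10)    # ceil_lg 5, ceil_two_lg 10
  expect_true(check_row(4, 9, b5)$mhl_check)    # deviation -1
  expect_true(check_row(6, 9, b5)$mhl_check)    # deviation +1
  expect_false(check_row(3, 9, b5)$mhl_check)   # deviation -2
  expect_false(check_row(7, 9, b5)$mhl_check)   # deviation +2
  expect_true(check_row(5, 10, b5)$mrl_check)   # mrl+1 = 11, dev +1
  expect_false(check_row(5, 7, b5)$mrl_check)   # mrl+1 = 8, dev -2

  # table rows from the reference experiments
  r <- check_row(4, 9, log_bounds(1e5, 10))
  expect_true(r$mhl_check && r$mrl_check)
  r <- check_row(5, 12, log_bounds(1.2e6, 10))  # mhl 5 vs ceil 7: fail
  expect_false(r$mhl_check)
  # standard ceiling: ceil(2 log10 1.2e6) = 13, so mrl+1 = 13 passes
  expect_equal(r$ceil_two_lg, 13L)
  expect_true(r$mrl_check)
  r <- check_row(4, 7, log_bounds(2e4, 10))
  expect_true(r$mhl_check)
  # ceil(2 log10 2e4) = 9: deviation of mrl+1 = 8 is -1, inside tolerance
  expect_equal(r$ceil_two_lg, 9L)
  expect_true(r$mrl_check)
  expect_equal(r$dev_mrl, -1)
})

test_that("hapax floor minus repeat ceiling is non-negative", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(1:10^7, 1)
    m <- sample(2:256, 1)
    expect_gte(predicted_hapax_floor(n, m), predicted_repeat_ceiling(n, m))
  }
})

test_that("prefix scan recomputes each prefix exactly and scores rows", {
  s <- uniform_string(5000, m = 10, seed = 99)
  r <- lbt(s, prefixes = c(100, 1000, 5000))
  expect_equal(nrow(r$rows), 3L)
  # each row equals a from-scratch computation on the prefix
  for (i in seq_len(3)) {
    p <- prefix(s, r$rows$n[i])
    idx <- suffix_index(p)
    expect_equal(r$rows$mhl[i], min_hapax_length(idx))
    expect_equal(r$rows$mrl_plus1[i], max_repeat_length(idx) + 1L)
  }
  expect_true(r$score >= 0 && r$score <= 1)
  expect_equal(r$score == 1, all(r$rows$mhl_check & r$rows$mrl_check))
  # deviation statistics match direct recomputation
  expect_equal(r$mean_dev_mhl, mean(r$rows$dev_mhl))
  expect_equal(r$sd_dev_mrl, sd(r$rows$dev_mrl))
  expect_error(lbt(s, prefixes = 10000), "prefix exceeds string")
})

test_that("a single ok prefix scores 1 and the default schedule is decades", {
  s <- uniform_string(1000, m = 10, seed = 3)
  idx <- suffix_index(s)
  r1 <- lbt(s, prefixes = 1000)
  manual <- check_row(min_hapax_length(idx), max_repeat_length(idx),
                      log_bounds(1000, 10))
  expect_equal(r1$score, as.numeric(manual$mhl_check && manual$mrl_check))

  expect_equal(default_prefixes(1e4), c(10, 20, 50, 100, 200, 500,
                                        1000, 2000, 5000, 10000))
  expect_equal(default_prefixes(30000), c(10, 20, 50, 100, 200, 500, 1000,
                                          2000, 5000, 10000, 20000, 30000))
})

test_that("score is invariant under row permutation", {
  s <- uniform_string(2000, m = 4, seed = 17)
  r <- lbt(s, prefixes = c(50, 200, 800, 2000))
  perm <- r$rows[c(3, 1, 4, 2), ]
  expect_equal(mean(perm$mhl_check & perm$mrl_check), r$score)
})

test_that("random strings concentrate near the logarithmic bounds", {
  # m = 4, n = 1e4: the longest repeat concentrates within a couple of
  # symbols of ceil(2LG); the shortest hapax sits just below ceil(LG)
  # (for m = 4 the typical value is ceil(LG) - 2, a known small-alphabet
  # offset of the hapax bound)
  m <- 4; n <- 1e4
  b <- log_bounds(n, m)
  ok_mrl <- ok_mhl <- logical(30)
  for (i in seq_len(30)) {
    idx <- suffix_index(uniform_string(n, m, seed = 1000 + i))
    ok_mrl[i] <- abs(max_repeat_length(idx) + 1 - b$ceil_two_lg) <= 2
    ok_mhl[i] <- min_hapax_length(idx) %in%
      ((b$ceil_lg - 2L):b$ceil_lg)
  }
  expect_gte(mean(ok_mrl), 0.9)
  expect_gte(mean(ok_mhl), 0.9)
})
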