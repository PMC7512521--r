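test_that("digit generators agree with the published expansions", {
  expect_equal(format(pi_digits(50)),
    "31415926535897932384626433832795028841971693993751")
  expect_equal(format(e_digits(50)),
    "27182818284590452353602874713526624977572470936999")
  expect_equal(format(sqrt2_digits(50)),
    "14142135623730950488016887242096980785696718753769")
  expect_equal(format(pi_digits(6)), "314159")
  expect_equal(format(sqrt2_digits(6)), "141421")
  expect_equal(pi_digits(10)$m, 10L)
})

test_that("champernowne digits concatenate the naturals", {
  expect_equal(format(champernowne_digits(10)), "1234567891")
  expect_equal(format(champernowne_digits(16)), "1234567891011121")
  # crosses the 2- to 3-digit boundary correctly: ...99100101...
  s <- format(champernowne_digits(200))
  expect_equal(substr(s, 187, 195), "899100101")
})

test_that("deterministic generators are prefix-stable", {
  long <- format(champernowne_digits(2000))
  expect_equal(format(champernowne_digits(500)), substr(long, 1, 500))
  # the digit cache serves prefixes of longer expansions
  p200 <- format(pi_digits(200))
  expect_equal(format(pi_digits(60)), substr(p200, 1, 60))
  e120 <- format(e_digits(120))
  expect_equal(format(e_digits(40)), substr(e120, 1, 40))
})

test_that("the logistic map iterates and bins as specified", {
  s <- logistic_string(3, x0 = 0.1, r = 4, m = 10)
  # x = 0.1, 0.36, 0.9216 -> symbols 1, 3, 9
  expect_equal(s$codes, c(1L, 3L, 9L))
  # fixed point of the map: constant symbol
  s <- logistic_string(50, x0 = 0.5, r = 2, m = 10)
  expect_equal(unique(s$codes), 5L)
  expect_error(logistic_string(10, x0 = 0), "x0")
  expect_error(logistic_string(10, r = 5), "r must be")
})

test_that("the LCG recurrence, presets and determinism behave", {
  s <- lcg_string(5, m = 10, seed = 0, preset = "none",
                  mult = 1, incr = 1, modulus = 10)
  expect_equal(s$codes, c(1L, 2L, 3L, 4L, 5L))
  a <- lcg_string(1000, seed = 42)
  b <- lcg_string(1000, seed = 42)
  expect_identical(a$codes, b$codes)
  expect_false(identical(a$codes, lcg_string(1000, seed = 43)$codes))
  expect_true(all(a$codes >= 0L & a$codes <= 9L))
})

test_that("uniform strings are seeded, reproducible and balanced", {
  a <- uniform_string(1e5, m = 2, seed = 5)
  b <- uniform_string(1e5, m = 2, seed = 5)
  expect_identical(a$codes, b$codes)
  # each symbol frequency within 3 sigma of n/2
  f <- sum(a$codes == 0L)
  expect_lt(abs(f - 5e4), 3 * sqrt(1e5 * 0.25))
  # caller RNG state is preserved
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(uniform_string(10, 2, seed = 9)); x2 <- runif(1)
  expect_equal(x1, x2)
})
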