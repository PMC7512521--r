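# The deterministic generators are prefix-stable: requesting a longer
# string extends, never alters, previously emitted symbols.  Constant-digit
# results are cached per session, so shorter requests slice the longest
# expansion computed so far.

digit_alphabet <- as.character(0:9)

cached_digits <- function(key, n, compute) {
  n <- as.numeric(n)
  if (n < 1) stop("n must be >= 1")
  cur <- get0(key, envir = .digit_cache)
  if (is.null(cur) || nchar(cur) < n) {
    cur <- compute(n)
    assign(key, cur, envir = .digit_cache)
  }
  symbol_string(substr(cur, 1, n), alphabet = digit_alphabet)
}

#' Decimal digits of pi, e and sqrt(2)
#'
#' The first `n` decimal digits of the constant, integer part included and
#' decimal point removed: pi starts `3141592653...`, e starts
#' `2718281828...`, sqrt(2) starts `1414213562...`.  Digits are computed by
#' exact arbitrary-precision arithmetic (Chudnovsky series with binary
#' splitting for pi; the factorial series for e; an integer Newton square
#' root for sqrt(2)) with guard digits, so every emitted digit is exact.
#' Results are cached per session and are prefix-stable.
#'
#' @param n Number of digits, `n >= 1`.
#' @return A [symbol_string()] over the digit alphabet (`m = 10`).
#' @examples
#' format(pi_digits(6))     # "314159"
#' format(sqrt2_digits(6))  # "141421"
#' @export
pi_digits <- function(n) cached_digits("pi", n, cpp_pi_digits)

#' @rdname pi_digits
#' @export
e_digits <- function(n) cached_digits("e", n, cpp_e_digits)

#' @rdname pi_digits
#' @export
sqrt2_digits <- function(n) cached_digits("sqrt2", n, cpp_sqrt2_digits)

#' Digits of Champernowne's constant
#'
#' The first `n` characters of `123456789101112...`, the concatenation of
#' the natural numbers in increasing order.  Normal in base 10 yet rich in
#' long internal repeats, which makes it a classic stress case for
#' repeat-based randomness checks.
#'
#' @inheritParams pi_digits
#' @return A [symbol_string()] over the digit alphabet (`m = 10`).
#' @examples
#' format(champernowne_digits(16))  # "1234567891011121"
#' @export
champernowne_digits <- function(n) {
  cached_digits("champernowne", n, function(n) {
    # count of integers needed: digits(1..k) = sum over lengths
    total <- 0
    k <- 0
    width <- 1
    block_start <- 1
    while (total < n) {
      block <- 9 * 10^(width - 1)            # integers of this width
      add <- block * width
      if (total + add >= n) {
        need <- ceiling((n - total) / width)
        k <- block_start + need - 1
        total <- total + need * width
      } else {
        total <- total + add
        k <- block_start + block - 1
      }
      block_start <- block_start * 10
      width <- width + 1
    }
    paste(seq_len(k), collapse = "")
  })
}

#' Discretized logistic-map string
#'
#' Iterates the logistic map `x[i+1] = r * x[i] * (1 - x[i])` in IEEE
#' double precision starting from `x0`, and emits one symbol per iterate
#' (starting with `x0` itself) by floor-binning into `m` equal intervals:
#' `symbol = floor(x * m)`, clipped to `m - 1`.  With `r = 4` the orbit is
#' chaotic but inherits structure from finite-precision arithmetic, which
#' the log-bounds test exposes as long repeats.
#'
#' @param n Number of symbols.
#' @param x0 Initial value in (0, 1); default 0.1.
#' @param r Map parameter in (0, 4]; default 4.
#' @param m Number of discretization bins (alphabet size), `m >= 2`.
#' @return A [symbol_string()] with declared alphabet size `m`.
#' @examples
#' head(logistic_string(3)$codes)  # 1 3 9  (x = 0.1, 0.36, 0.9216)
#' @export
logistic_string <- function(n, x0 = 0.1, r = 4, m = 10) {
  n <- as.numeric(n)
  if (n < 1) stop("n must be >= 1")
  if (x0 <= 0 || x0 >= 1) stop("x0 must be in (0, 1)")
  if (r <= 0 || r > 4) stop("r must be in (0, 4]")
  if (m < 2) stop("m must be >= 2")
  x <- numeric(n)
  x[1] <- x0
  for (i in seq_len(n - 1)) {
    xi <- x[i]
    x[i + 1] <- r * xi * (1 - xi)
  }
  if (any(x <= 0 | x >= 1)) {
    warning("logistic orbit reached the interval boundary (degenerate orbit)")
  }
  codes <- pmin(as.integer(floor(x * m)), m - 1L)
  codes <- pmax(codes, 0L)
  alph <- if (m <= 10) digit_alphabet[seq_len(m)] else as.character(0:(m - 1))
  new_symbol_string(codes, alph, as.integer(m))
}

#' Linear congruential generator string
#'
#' Iterates `x[i+1] = (mult * x[i] + incr) mod modulus` and emits
#' `floor(m * x[i+1] / modulus)` per step (the seed state itself is not
#' emitted).  The `"java"` preset uses the multiplier 25214903917,
#' increment 11 and modulus 2^48 of the Java linear congruential
#' generator.  Output is bit-reproducible for given parameters and seed.
#'
#' @param n Number of symbols.
#' @param m Output alphabet size, `m >= 2`.
#' @param seed Initial state (non-negative integer below `modulus`).
#' @param preset `"java"` (default) or `"none"` to supply `mult`, `incr`,
#'   `modulus` explicitly.
#' @param mult,incr,modulus Recurrence parameters (used when
#'   `preset = "none"`); all must be exactly representable in a double.
#' @return A [symbol_string()] with declared alphabet size `m`.
#' @examples
#' # xn+1 = xn + 1 mod 10: symbols cycle 1, 2, 3, ...
#' head(lcg_string(5, m = 10, seed = 0, preset = "none",
#'                 mult = 1, incr = 1, modulus = 10)$codes)
#' @export
lcg_string <- function(n, m = 10, seed = 1, preset = c("java", "none"),
                       mult = NULL, incr = NULL, modulus = NULL) {
  preset <- match.arg(preset)
  n <- as.numeric(n)
  if (n < 1) stop("n must be >= 1")
  if (m < 2) stop("m must be >= 2")
  if (preset == "java") {
    mult <- 25214903917
    incr <- 11
    modulus <- 2^48
  }
  if (is.null(mult) || is.null(incr) || is.null(modulus)) {
    stop("mult, incr and modulus are required when preset = \"none\"")
  }
  if (modulus < 2) stop("modulus must be >= 2")
  codes <- cpp_lcg_codes(n, as.integer(m), mult, incr, modulus,
                         as.numeric(seed))
  alph <- if (m <= 10) digit_alphabet[seq_len(m)] else as.character(0:(m - 1))
  new_symbol_string(codes, alph, as.integer(m))
}

#' Uniform i.i.d. symbol string
#'
#' Independent uniform draws over `m` symbols from R's random number
#' generator; the model string family for the log-bounds test (a Bernoulli
#' scheme when `m = 2`).  Reproducible for a given `seed`.
#'
#' @param n Number of symbols.
#' @param m Alphabet size, `m >= 2`.
#' @param seed Optional integer seed; when given, the RNG state of the
#'   caller is preserved.
#' @return A [symbol_string()] with declared alphabet size `m`.
#' @export
uniform_string <- function(n, m, seed = NULL) {
  n <- as.numeric(n)
  if (n < 1) stop("n must be >= 1")
  if (m < 2) stop("m must be >= 2")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    set.seed(seed)
  }
  codes <- sample.int(m, n, replace = TRUE) - 1L
  alph <- if (m <= 10) digit_alphabet[seq_len(m)] else as.character(0:(m - 1))
  new_symbol_string(codes, alph, as.integer(m))
}
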