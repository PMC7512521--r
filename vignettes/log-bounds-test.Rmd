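---
title: "Informational indexes and the log-bounds randomness test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informational indexes and the log-bounds randomness test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logbounds)
```

## The indexes

For a string $\alpha$ of length $n$ over an alphabet of $m$ symbols, write
$\mathrm{mult}_\alpha(\beta)$ for the number of (possibly overlapping)
occurrences of a substring $\beta$.  A *repeat* is a substring with
multiplicity greater than one; a *hapax* is a substring with multiplicity
exactly one.  The package computes:

* **mrl** — maximum repeat length, the length of the longest repeat;
  defined as 0 when no substring repeats (all symbols distinct).
* **mhl** — minimum hapax length, the length of the shortest hapax;
  always defined because the whole string occurs once, so
  $1 \le \mathrm{mhl} \le n$.
* **mcl** — maximum complete length, the largest $k$ such that all $m^k$
  possible $k$-mers occur; 0 when a declared symbol is absent.
* **$E_k$** — the empirical $k$-entropy: Shannon entropy, base-$m$
  logarithm, of $p(w) = \mathrm{mult}_\alpha(w)/(n-k+1)$ over the distinct
  $k$-mers.

Two structural facts make these indexes coherent: every substring of a
repeat is a repeat, and every extension (within $\alpha$) of a hapax is a
hapax.  Consequently all $k$-mers with $k > \mathrm{mrl}$ are hapaxes, all
$k$-mers with $k < \mathrm{mhl}$ are repeats, $\mathrm{mhl} \ge
\mathrm{mcl}$, and $\mathrm{mcl} \le \lceil \log_m n \rceil$.  The test
suite asserts each of these on every string family it touches.

## The log-bounds test

For a string drawn symbol-wise uniformly at random, equiprobability of the
$m^k$ words of length $k$ pins both indexes near logarithmic reference
points.  Matching the number of available positions $n-k+1$ against the
$m^k$ words (a birthday-problem argument) gives the two reference values

$$\lceil LG \rceil = \lceil \log_m n \rceil, \qquad
  \lceil 2LG \rceil = \lceil 2\log_m n \rceil :$$

a random string should satisfy $\mathrm{mhl} \le \lceil LG \rceil$ (some
word of that length already occurs exactly once) and $\mathrm{mrl}+1 =
\lceil 2LG \rceil$ (no word of that length has room to occur twice).  The
log-bounds test applies this prefix-wise: for each prefix length in a
schedule, it computes `mhl` and `mrl` on the prefix and marks the prefix
as random-looking when

* `|mhl - ceiling(LG)| <= 1`, and
* `|mrl + 1 - ceiling(2LG)| <= 1`.

The aggregate score is the fraction of prefixes passing both checks;
signed deviations are summarised by mean and standard deviation.  No
p-value is attached: the test is a structural diagnostic, not a
significance test.

```{r}
r <- lbt(uniform_string(1e5, m = 10, seed = 42))
summary(r)
```

Non-random structure is conspicuous.  Champernowne's constant
`1234567891011121314...` is normal in base 10, yet its construction plants
long internal repeats, and `mrl + 1` drifts far above the bound while
`mhl` stays compliant:

```{r}
print(lbt(champernowne_digits(1e5)))
```

## Design choices

**Ceiling convention.**  `ceiling(LG)` is the standard mathematical
ceiling, computed by exact integer arithmetic (repeated ceiling division),
so $n = m^j$ yields exactly $j$ with no floating-point drift.  A reading
of "the smallest integer following the value" that adds 1 at integer $LG$
would contradict the reference results at $n = 100, 1000, \dots$ over
$m = 10$; we use the standard ceiling throughout.  Note that some
tabulations compute the doubled bound as twice the rounded single bound,
$2\lceil LG \rceil$, instead of $\lceil 2LG \rceil$; the two differ
whenever $\lceil 2\log_m n\rceil$ is odd (e.g. $n = 2\cdot 10^4$,
$m = 10$: $\lceil 8.60 \rceil = 9$ versus $2\cdot 5 = 10$), which can
flip a marginal ±1 check.  The derivation that motivates the bound pins
down $\lceil 2\log_m n \rceil$, so that is what `log_bounds()` reports.

**The ±1 tolerance.**  The pass rule is a symmetric absolute deviation of
at most 1 on both comparisons.  Deviations are also reported signed, so a
user can distinguish a repeat excess (structure) from a shortfall.

**Overlaps count.**  Multiplicity counts overlapping occurrences
(`"aa"` occurs 4 times in `"aaaaa"`), consistent with the denominator
$n-k+1$ of the empirical distribution.

**Alphabet size is declared, not observed.**  $m$ defaults to the number
of distinct symbols present, but every reader and the test accept an
override, because nominal alphabets matter in practice (256 for raw
bytes, 4 for DNA, 26 for case-folded letters): a string that happens to
miss a symbol should still be judged against its nominal alphabet.
`m = 1` is rejected wherever a logarithm is taken; counting indexes still
work (a single-support entropy is 0 in every base).

**Prefixes are recomputed from scratch.**  Each checkpoint rebuilds the
suffix structure on the prefix.  This is simple and exact; an incremental
mode would be an optimisation, not a semantic change.  The default
schedule is the decade/half-decade grid $\{10^j, 2\cdot 10^j,
5\cdot 10^j\}$ capped at $n$, plus $n$ itself.

## The suffix-array backend

All indexes are answered from a suffix array (SA-IS, linear time, integer
alphabet) plus an LCP array (Kasai).  `mrl` is the maximum adjacent LCP;
`mhl` is the minimum over positions of one plus the larger neighbour LCP,
clipped to fit before the string end; $|D_k|$, hapax/repeat counts and
$E_k$ come from runs in the LCP array at threshold $k$.  A suffix
structure was chosen over hashing so the indexes are exact rather than
probabilistic; every query path is verified against naive enumeration of
all substrings on hundreds of random strings (up to $n = 2000$, $m \in
\{2, 4, 10, 26\}$) in the test suite.  Entropy comparisons use an
absolute tolerance of $10^{-9}$; all other quantities are integers and
compared exactly.

## Generators: what they emulate

The generator module reproduces, without any download, the string
families on which the test was calibrated:

* `pi_digits`, `e_digits`, `sqrt2_digits` — exact decimal digits,
  integer part included and decimal point removed (`3141...`, `2718...`,
  `1414...`).  π uses the Chudnovsky series with binary splitting; e the
  factorial series in a Horner recurrence; √2 an exact integer Newton
  square root of $2\cdot 10^{2(n-1)}$.  The backend is a base-$10^9$
  bignum with Karatsuba multiplication, Knuth division and
  multiplication-only Newton reciprocal/rsqrt with precision doubling.
  40 guard digits absorb truncation error, and a run of 0s or 9s crossing
  the guard boundary triggers recomputation at higher precision, so every
  emitted digit is exact.  Including the integer-part digit is a
  convention; at the scales tested the repeat/hapax witnesses are
  interior to the string, so dropping one leading symbol does not move
  the indexes (asserted in the tests at small scale by prefix-stability).
* `champernowne_digits` — the concatenation `123456789101112...`.
* `logistic_string` — $x_{i+1} = r x_i (1-x_i)$ iterated in IEEE double
  precision from `x0` (default 0.1, `r = 4`), emitting
  $\lfloor m x_i \rfloor$ for every iterate *including* $x_0$.  Whether
  $x_0$ itself is emitted, and the exact floor-binning, are choices; the
  reproduced repeat lengths at $n = 1000$ are stable under the choice of
  offset on this platform, but the chaotic tail of the orbit depends on
  the floating-point environment, so logistic results are
  platform-deterministic rather than mathematically canonical.
* `lcg_string` — $x_{n+1} = (c\,x_n + b) \bmod M$ with the Java preset
  $c = 25214903917$, $b = 11$, $M = 2^{48}$, binned to $m$ symbols by
  $\lfloor m x / M \rfloor$.  The reference experiments do not state a
  seed; the reproduced quantity (`mhl` at $n = 10^6$) is seed-robust,
  and the package treats it as such (checked over 10 seeds).
* `uniform_string` — i.i.d. uniform symbols from R's RNG, the ideal
  model family.  At $m = 4$, $n = 10^5$, `mrl + 1` concentrates on
  $\lceil 2LG \rceil \pm 1$, but not overwhelmingly: a Poisson clumping
  estimate puts the probability of a repeat one symbol beyond the band
  at about 5% and of a shortfall at about 3%, so roughly nine in ten
  replicates land inside.  For the same small-alphabet reason `mhl`
  typically sits at $\lceil LG \rceil - 2$ when $m = 4$, one below the
  band that holds for the decimal and larger alphabets.

What the generated families do *not* emulate: empirical corpora (natural
language, genomes, physical random bytes, roulette records).  Those are
supported through the plain-text/byte and FASTA readers with nominal
alphabet overrides, but no corpus is bundled, so conclusions about such
data require the user's own files.  Passing tests on the generated
families therefore demonstrates correctness of the machinery and
reproduction of the mathematical-constant results, not any claim about
empirical sources.

## Problem sizes and costs

The package's own verification uses: digits of π to $10^6$ (≈25 s of
bignum arithmetic), e to $2\cdot 10^5$, √2 to $10^5$, Champernowne to
$10^7$ (suffix array ≈6 s), LCG strings of $10^6$ over 10 seeds, and 50
uniform replicates at $10^5$.  Suffix-array construction is linear-time
and handles $10^7$ symbols in a few seconds; the digit generators are the
dominant cost and scale slightly above linearly in the digit count.

## Limitations

* The test yields a score and deviations, not a p-value; it cannot
  certify randomness (no finite test can), only flag structure.
* Logistic-map strings inherit the platform's floating-point behaviour.
* The per-prefix recomputation makes a long schedule on a very long
  string quadratic in the worst case; thin the schedule for
  $n \gg 10^7$.
* Index values at very small $n$ (below ~100) are dominated by edge
  effects and excluded from the package's reference checks.
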