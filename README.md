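# logbounds

Informational indexes and the log-bounds randomness test for finite
symbol strings.

## What it is for

Given a finite string α of length *n* over an alphabet of *m* symbols,
the package computes its *informational indexes* exactly:

* **mrl** — maximum repeat length: the length of the longest substring
  occurring more than once (overlaps count);
* **mhl** — minimum hapax length: the length of the shortest substring
  occurring exactly once;
* **mcl** — maximum complete length: the largest *k* such that all *m^k*
  possible *k*-mers occur;
* **E_k** — the empirical *k*-entropy: Shannon entropy, base-*m*, of
  p(w) = mult(w)/(n−k+1) over the distinct *k*-mers.

For a string drawn uniformly at random these indexes are pinned near two
logarithmic reference values, `⌈LG⌉ = ⌈log_m n⌉` and
`⌈2LG⌉ = ⌈2 log_m n⌉`: a random string should satisfy `mhl ≤ ⌈LG⌉` and
`mrl + 1 = ⌈2LG⌉`.  The **log-bounds test** (`lbt()`) checks both
coincidences, with a ±1 tolerance, on a schedule of prefixes, and scores
the fraction of prefixes passing.  Strings with planted structure —
natural language, genomes, Champernowne's constant, logistic-map orbits —
blow through the repeat bound; good pseudo-random and
mathematical-constant digit strings sit on it.

Everything is computed from a linear-time suffix array (SA-IS) with an
LCP array, so strings of 10^7 symbols are routine.  The package also
generates, offline and exactly, the classical test families: decimal
digits of π, *e* and √2 (own arbitrary-precision engine), Champernowne's
constant, logistic-map discretizations, linear congruential generators
(Java preset included) and uniform i.i.d. strings — plus plain-text,
byte and FASTA readers for user corpora.

## Worked example

```r
library(logbounds)

r <- lbt(pi_digits(1e5), prefixes = c(1000, 10000, 100000))
print(r)
#> Log-bounds randomness test  (n = 100,000, m = 10)
#>
#>        n mhl ceil(LG) check mrl+1 ceil(2LG) check
#>    1,000   3        3     ✓     6         6     ✓
#>   10,000   4        4     ✓     8         8     ✓
#>  100,000   4        5     ✓    10        10     ✓
#>
#> score: 1.000  (3/3 prefixes pass both checks)
```

Every prefix of π's digits passes both checks: the shortest unique
substring (`mhl`) tracks `⌈LG⌉` and the longest repeat stays one short
of `⌈2LG⌉` — the signature of a random-looking string.  Champernowne's
constant `123456789101112...` is the standard counterexample: normal in
base 10, but its construction plants long repeats,

```r
print(lbt(champernowne_digits(1e5), prefixes = c(1000, 10000, 100000)))
#>        n mhl ceil(LG) check mrl+1 ceil(2LG) check
#>    1,000   3        3     ✓     6         6     ✓
#>   10,000   4        4     ✓     9         8     ✓
#>  100,000   5        5     ✓    12        10     ✗
#>
#> score: 0.667  (2/3 prefixes pass both checks)
```

and at 10^5 digits its longest repeat is already 11 symbols
(`mrl+1 = 12`) against a reference of 10.  The per-string index profile:

```r
index_profile("banana")
#> <index_profile> n = 6, m = 3
#>   mrl = 3   mhl = 1   mcl = 1
#>  k distinct hapax repeats   entropy complete
#>  1        3     1       2 0.9206198     TRUE
#>  2        3     1       2 0.9602297    FALSE
#>  3        3     2       1 0.9463946    FALSE
#>  4        3     3       0 1.0000000    FALSE
```

(`mrl = 3`: "ana" occurs twice, overlapping; `mhl = 1`: "b" occurs once;
`mcl = 1`: all three symbols occur but only 3 of the 9 possible 2-mers.)

Reports serialize to TSV/JSON (`write_lbt()` / `read_lbt()`), and a thin
command-line front end lives at `inst/cli/lbt`
(`lbt analyze`, `lbt generate`, `lbt selftest`).

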