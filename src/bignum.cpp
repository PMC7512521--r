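// Exact decimal-digit generators for pi, e and sqrt(2).
//
// Fixed-precision decimal arithmetic on a base-1e9 bignum: Karatsuba
// multiplication, Knuth Algorithm-D division, integer Newton square root.
// pi uses Chudnovsky's series with binary splitting; e uses the factorial
// series evaluated by a Horner recurrence; sqrt(2) is the integer square
// root of 2 * 10^(2(n-1)), whose decimal expansion is the truncated digit
// expansion of sqrt(2) (exact, since sqrt(2) is irrational).
//
// Emitted digits are exact: series truncation and rounding errors are
// confined to guard digits, and a run of 0s or 9s crossing the guard
// boundary triggers a recomputation at higher precision.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>

namespace {

typedef std::vector<uint32_t> Big; // base 1e9, little endian, no leading zeros
const uint64_t BASE = 1000000000ull;

void trim(Big &a) {
    while (!a.empty() && a.back() == 0u) a.pop_back();
}

Big from_u64(uint64_t v) {
    Big r;
    while (v) { r.push_back((uint32_t)(v % BASE)); v /= BASE; }
    return r;
}

int cmp(const Big &a, const Big &b) {
    if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
    for (size_t i = a.size(); i-- > 0;)
        if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
    return 0;
}

Big add(const Big &a, const Big &b) {
    const Big &x = a.size() >= b.size() ? a : b;
    const Big &y = a.size() >= b.size() ? b : a;
    Big r(x.size() + 1, 0u);
    uint64_t carry = 0;
    for (size_t i = 0; i < x.size(); ++i) {
        uint64_t cur = carry + x[i] + (i < y.size() ? y[i] : 0u);
        r[i] = (uint32_t)(cur % BASE);
        carry = cur / BASE;
    }
    r[x.size()] = (uint32_t)carry;
    trim(r);
    return r;
}

// requires a >= b
Big sub(const Big &a, const Big &b) {
    Big r(a.size(), 0u);
    int64_t borrow = 0;
    for (size_t i = 0; i < a.size(); ++i) {
        int64_t cur = (int64_t)a[i] - (i < b.size() ? (int64_t)b[i] : 0) + borrow;
        if (cur < 0) { r[i] = (uint32_t)(cur + (int64_t)BASE); borrow = -1; }
        else         { r[i] = (uint32_t)cur; borrow = 0; }
    }
    trim(r);
    return r;
}

Big mul_small(const Big &a, uint32_t m) {
    if (m == 0 || a.empty()) return Big();
    Big r(a.size() + 1, 0u);
    uint64_t carry = 0;
    for (size_t i = 0; i < a.size(); ++i) {
        uint64_t cur = (uint64_t)a[i] * m + carry;
        r[i] = (uint32_t)(cur % BASE);
        carry = cur / BASE;
    }
    r[a.size()] = (uint32_t)carry;
    trim(r);
    return r;
}

// in-place divide by small d (d < 2^32), returns remainder
uint32_t div_small(Big &a, uint32_t d) {
    uint64_t rem = 0;
    for (size_t i = a.size(); i-- > 0;) {
        uint64_t cur = rem * BASE + a[i];
        a[i] = (uint32_t)(cur / d);
        rem = cur % d;
    }
    trim(a);
    return (uint32_t)rem;
}

Big shl_limbs(const Big &a, size_t s) {
    if (a.empty()) return a;
    Big r(a.size() + s, 0u);
    std::copy(a.begin(), a.end(), r.begin() + s);
    return r;
}

Big mul_school(const Big &a, const Big &b) {
    Big r(a.size() + b.size(), 0u);
    for (size_t i = 0; i < a.size(); ++i) {
        uint64_t ai = a[i];
        if (!ai) continue;
        uint64_t carry = 0;
        for (size_t j = 0; j < b.size(); ++j) {
            uint64_t cur = r[i + j] + ai * b[j] + carry;
            r[i + j] = (uint32_t)(cur % BASE);
            carry = cur / BASE;
        }
        size_t k = i + b.size();
        while (carry) {
            uint64_t cur = r[k] + carry;
            r[k] = (uint32_t)(cur % BASE);
            carry = cur / BASE;
            ++k;
        }
    }
    trim(r);
    return r;
}

Big mul(const Big &a, const Big &b) {
    if (a.empty() || b.empty()) return Big();
    if (std::min(a.size(), b.size()) <= 32) return mul_school(a, b);
    size_t h = std::max(a.size(), b.size()) / 2;
    Big a0(a.begin(), a.begin() + std::min(h, a.size()));
    Big a1 = a.size() > h ? Big(a.begin() + h, a.end()) : Big();
    Big b0(b.begin(), b.begin() + std::min(h, b.size()));
    Big b1 = b.size() > h ? Big(b.begin() + h, b.end()) : Big();
    trim(a0); trim(b0);
    Big z0 = mul(a0, b0);
    Big z2 = mul(a1, b1);
    Big z1 = sub(mul(add(a0, a1), add(b0, b1)), add(z0, z2));
    Big r = add(z0, shl_limbs(z1, h));
    r = add(r, shl_limbs(z2, 2 * h));
    return r;
}

// Knuth Algorithm D; returns quotient, remainder discarded unless asked.
Big divmod(const Big &u0, const Big &v0, Big *rem_out = 0) {
    if (v0.empty()) Rcpp::stop("division by zero");
    if (cmp(u0, v0) < 0) {
        if (rem_out) *rem_out = u0;
        return Big();
    }
    if (v0.size() == 1) {
        Big q = u0;
        uint32_t r = div_small(q, v0[0]);
        if (rem_out) *rem_out = from_u64(r);
        return q;
    }
    uint32_t d = (uint32_t)(BASE / ((uint64_t)v0.back() + 1));
    Big u = mul_small(u0, d);
    Big v = mul_small(v0, d);
    size_t n = v.size();
    if (u.size() < n) { if (rem_out) *rem_out = u0; return Big(); }
    size_t m = u.size() - n;
    u.push_back(0u);
    Big q(m + 1, 0u);
    for (size_t jj = m + 1; jj-- > 0;) {
        size_t j = jj;
        unsigned __int128 num =
            (unsigned __int128)u[j + n] * BASE + u[j + n - 1];
        uint64_t qhat = (uint64_t)(num / v[n - 1]);
        uint64_t rhat = (uint64_t)(num % v[n - 1]);
        while (qhat >= BASE ||
               (unsigned __int128)qhat * v[n - 2] >
                   (unsigned __int128)rhat * BASE + u[j + n - 2]) {
            --qhat;
            rhat += v[n - 1];
            if (rhat >= BASE) break;
        }
        // multiply and subtract
        int64_t borrow = 0;
        uint64_t carry = 0;
        for (size_t i = 0; i < n; ++i) {
            uint64_t p = qhat * v[i] + carry;
            carry = p / BASE;
            int64_t t = (int64_t)u[j + i] - (int64_t)(p % BASE) + borrow;
            if (t < 0) { u[j + i] = (uint32_t)(t + (int64_t)BASE); borrow = -1; }
            else       { u[j + i] = (uint32_t)t; borrow = 0; }
        }
        int64_t t = (int64_t)u[j + n] - (int64_t)carry + borrow;
        if (t < 0) { u[j + n] = (uint32_t)(t + (int64_t)BASE); borrow = -1; }
        else       { u[j + n] = (uint32_t)t; borrow = 0; }
        if (borrow) { // add back (rare)
            --qhat;
            uint64_t c2 = 0;
            for (size_t i = 0; i < n; ++i) {
                uint64_t s2 = (uint64_t)u[j + i] + v[i] + c2;
                u[j + i] = (uint32_t)(s2 % BASE);
                c2 = s2 / BASE;
            }
            u[j + n] = (uint32_t)(((uint64_t)u[j + n] + c2) % BASE);
        }
        q[j] = (uint32_t)qhat;
    }
    trim(q);
    if (rem_out) {
        Big r(u.begin(), u.begin() + n);
        trim(r);
        div_small(r, d);
        *rem_out = r;
    }
    return q;
}

uint64_t to_u64(const Big &a) {
    uint64_t v = 0;
    for (size_t i = a.size(); i-- > 0;) v = v * BASE + a[i];
    return v;
}

// floor(sqrt(N)), exact.  Recursive halving seed + integer Newton descent.
Big isqrt_big(const Big &N) {
    if (N.empty()) return Big();
    if (N.size() <= 2) {
        uint64_t v = to_u64(N);
        uint64_t x = (uint64_t)std::sqrt((double)v);
        while (x > 0 && x * x > v) --x;
        while ((x + 1) * (x + 1) <= v) ++x;
        return from_u64(x);
    }
    size_t s = std::max<size_t>(1, N.size() / 4);
    Big N1(N.begin() + 2 * s, N.end());
    Big x1 = isqrt_big(N1);
    Big x = shl_limbs(add(x1, from_u64(1)), s); // upper bound for sqrt(N)
    for (;;) {
        Big y = divmod(N, x);
        Big x2 = add(x, y);
        div_small(x2, 2);
        if (cmp(x2, x) >= 0) break;
        x = x2;
    }
    return x;
}

// drop the s lowest limbs (floor division by B^s)
Big shr_limbs(const Big &a, size_t s) {
    if (a.size() <= s) return Big();
    return Big(a.begin() + s, a.end());
}

// Newton reciprocal, multiplication-only with precision doubling:
// returns R with R ≈ B^(t+p) / T (t = limb count of T), relative error
// a few units in the last limb.  Only the top p+3 limbs of T matter at
// accuracy p, so operands stay O(p) limbs and the cost is O(M(p)).
Big recip_approx(const Big &T, size_t p) {
    size_t t = T.size();
    size_t keep = std::min(t, p + 3);
    Big Th(T.end() - keep, T.end());
    // B^(t+p)/T = B^(keep+p)/Th up to relative error < B^-(keep-1)
    if (p <= 8) return divmod(shl_limbs(from_u64(1), keep + p), Th);
    size_t ph = p / 2 + 2;
    Big Rh = recip_approx(Th, ph); // ≈ B^(keep+ph)/Th
    // Newton step: R = 2·Rh·B^(p-ph) − Th·Rh² / B^(2ph + keep − p)
    Big term1 = shl_limbs(mul_small(Rh, 2u), p - ph);
    Big term2 = shr_limbs(mul(Th, mul(Rh, Rh)), 2 * ph + keep - p);
    return sub(term1, term2);
}

// floor(N/T) up to an error of a few units in the last limb (the guard
// digits of the callers absorb it)
Big div_approx(const Big &N, const Big &T) {
    if (cmp(N, T) < 0) return Big();
    size_t t = T.size();
    size_t p = N.size() - t + 3;
    Big R = recip_approx(T, p); // ≈ B^(t+p)/T
    return shr_limbs(mul(N, R), t + p);
}

// ≈ B^p / sqrt(A) for a small integer A >= 2, same accuracy contract
Big rsqrt_small(uint32_t A, size_t p) {
    if (p <= 6) {
        Big s = isqrt_big(shl_limbs(from_u64(A), 2 * p)); // sqrt(A)·B^p
        return divmod(shl_limbs(from_u64(1), 2 * p), s);
    }
    size_t ph = p / 2 + 2;
    Big y = shl_limbs(rsqrt_small(A, ph), p - ph);
    // Newton: y' = y·(3·B^(2p) − A·y²) / (2·B^(2p))
    Big z = sub(shl_limbs(from_u64(3), 2 * p), mul_small(mul(y, y), A));
    Big r = shr_limbs(mul(y, z), 2 * p);
    div_small(r, 2);
    return r;
}

std::string to_decimal(const Big &a) {
    if (a.empty()) return "0";
    char buf[16];
    std::string s;
    s.reserve(a.size() * 9);
    snprintf(buf, sizeof(buf), "%u", a.back());
    s += buf;
    for (size_t i = a.size() - 1; i-- > 0;) {
        snprintf(buf, sizeof(buf), "%09u", a[i]);
        s += buf;
    }
    return s;
}

Big pow10_big(size_t decimal_digits) {
    size_t limbs = decimal_digits / 9, r = decimal_digits % 9;
    uint32_t top = 1;
    for (size_t i = 0; i < r; ++i) top *= 10;
    Big p(limbs, 0u);
    p.push_back(top);
    trim(p);
    return p;
}

// digits beyond position n are a run of 0s or 9s: rounding could reach
// into the emitted prefix, so the caller must retry with more guards
bool guard_suspect(const std::string &digits, size_t n) {
    if (digits.size() < n + 12) return true;
    char c0 = digits[n];
    if (c0 != '0' && c0 != '9') return false;
    for (size_t i = n; i < n + 12; ++i)
        if (digits[i] != c0) return false;
    return true;
}

// ---- Chudnovsky binary splitting -------------------------------------

struct SBig { Big v; int s; }; // signed magnitude, s in {+1,-1}

SBig sadd(const SBig &a, const SBig &b) {
    if (a.s == b.s) return SBig{add(a.v, b.v), a.s};
    int c = cmp(a.v, b.v);
    if (c == 0) return SBig{Big(), 1};
    if (c > 0) return SBig{sub(a.v, b.v), a.s};
    return SBig{sub(b.v, a.v), b.s};
}

void chud_split(uint64_t a, uint64_t b, Big &P, Big &Q, SBig &T) {
    if (b - a == 1) {
        if (a == 0) {
            P = from_u64(1);
            Q = from_u64(1);
            T = SBig{from_u64(13591409ull), 1};
        } else {
            uint64_t p64 = (6 * a - 5) * (2 * a - 1) * (6 * a - 1);
            P = from_u64(p64);
            Q = mul(from_u64(a * a * a), from_u64(10939058860032000ull));
            T.v = mul(P, from_u64(13591409ull + 545140134ull * a));
            T.s = (a & 1) ? -1 : 1;
        }
        return;
    }
    uint64_t m = a + (b - a) / 2;
    Big P1, Q1, P2, Q2;
    SBig T1, T2;
    chud_split(a, m, P1, Q1, T1);
    chud_split(m, b, P2, Q2, T2);
    P = mul(P1, P2);
    Q = mul(Q1, Q2);
    SBig left{mul(T1.v, Q2), T1.s};
    SBig right{mul(P1, T2.v), T2.s};
    T = sadd(left, right);
}

std::string pi_digits_impl(size_t n, size_t guard) {
    size_t prec = n + guard;                       // working decimal digits
    size_t lp = prec / 9 + 2;                      // working limbs
    uint64_t terms = (uint64_t)(prec / 14.181647462725477) + 3;
    Big P, Q;
    SBig T;
    chud_split(0, terms, P, Q, T);
    // pi = 426880 * sqrt(10005) * Q / T
    Big sq = mul_small(rsqrt_small(10005u, lp), 10005u); // sqrt(10005)·B^lp
    Big num = mul(Q, sq);
    num = mul_small(num, 426880u);
    Big pif = div_approx(num, T.v); // T(0,N) > 0: first term dominates
    // value ≈ pi·B^lp; render and cut to the decimal point + prec digits
    std::string d = to_decimal(pif);
    return d.substr(0, 1 + prec); // "3" + prec fractional digits
}

std::string e_digits_impl(size_t n, size_t guard) {
    size_t prec = n + guard;
    // smallest K with K! > 10^prec
    uint64_t K = 2;
    while (std::lgamma((double)K + 1.0) <= prec * std::log(10.0)) ++K;
    Big one = pow10_big(prec);
    Big acc = one;
    for (uint64_t k = K; k >= 1; --k) {
        div_small(acc, (uint32_t)k);
        acc = add(acc, one);
    }
    return to_decimal(acc); // "2" + prec fractional digits (approx)
}

} // namespace

// [[Rcpp::export]]
std::string cpp_pi_digits(double n) {
    size_t need = (size_t)n;
    size_t guard = 40;
    for (int attempt = 0; attempt < 4; ++attempt, guard += 60) {
        std::string d = pi_digits_impl(need, guard);
        if (d.size() >= need + 12 && !guard_suspect(d, need))
            return d.substr(0, need);
    }
    Rcpp::stop("pi digit computation failed to stabilize");
}

// [[Rcpp::export]]
std::string cpp_e_digits(double n) {
    size_t need = (size_t)n;
    size_t guard = 40;
    for (int attempt = 0; attempt < 4; ++attempt, guard += 60) {
        std::string d = e_digits_impl(need, guard);
        if (d.size() >= need + 12 && !guard_suspect(d, need))
            return d.substr(0, need);
    }
    Rcpp::stop("e digit computation failed to stabilize");
}

// [[Rcpp::export]]
std::string cpp_sqrt2_digits(double n) {
    // floor(sqrt(2) * 10^(n-1)) is exactly the first n digits of sqrt(2)
    size_t need = (size_t)n;
    Big N = mul_small(pow10_big(2 * (need - 1)), 2u);
    std::string d = to_decimal(isqrt_big(N));
    return d.substr(0, need);
}
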