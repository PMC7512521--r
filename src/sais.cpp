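// Linear-time suffix array (SA-IS, Nong-Zhang-Chan) over an integer
// alphabet, plus Kasai's LCP construction and a suffix-array binary
// search used for substring multiplicity queries.

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using Rcpp::IntegerVector;
using Rcpp::List;

namespace {

inline bool is_lms(const std::vector<uint8_t> &t, int i) {
    return i > 0 && t[i] && !t[i - 1];
}

void get_buckets(const int *s, int *bkt, int n, int K, bool end) {
    for (int i = 0; i <= K; ++i) bkt[i] = 0;
    for (int i = 0; i < n; ++i) bkt[s[i]]++;
    int sum = 0;
    for (int i = 0; i <= K; ++i) {
        sum += bkt[i];
        bkt[i] = end ? sum : sum - bkt[i];
    }
}

void induce_l(const std::vector<uint8_t> &t, int *SA, const int *s,
              int *bkt, int n, int K) {
    get_buckets(s, bkt, n, K, false);
    for (int i = 0; i < n; ++i) {
        int j = SA[i] - 1;
        if (SA[i] > 0 && j >= 0 && !t[j]) SA[bkt[s[j]]++] = j;
    }
}

void induce_s(const std::vector<uint8_t> &t, int *SA, const int *s,
              int *bkt, int n, int K) {
    get_buckets(s, bkt, n, K, true);
    for (int i = n - 1; i >= 0; --i) {
        int j = SA[i] - 1;
        if (SA[i] > 0 && j >= 0 && t[j]) SA[--bkt[s[j]]] = j;
    }
}

// s[0..n-1] with s[n-1] = 0 the unique sentinel; K = max symbol
void sa_is(const int *s, int *SA, int n, int K) {
    std::vector<uint8_t> t(n);
    t[n - 1] = 1; // sentinel is S-type
    if (n > 1) t[n - 2] = 0;
    for (int i = n - 3; i >= 0; --i)
        t[i] = (s[i] < s[i + 1] || (s[i] == s[i + 1] && t[i + 1])) ? 1 : 0;

    std::vector<int> bkt(K + 1);
    for (int i = 0; i < n; ++i) SA[i] = -1;
    get_buckets(s, bkt.data(), n, K, true);
    for (int i = 1; i < n; ++i)
        if (is_lms(t, i)) SA[--bkt[s[i]]] = i;
    induce_l(t, SA, s, bkt.data(), n, K);
    induce_s(t, SA, s, bkt.data(), n, K);

    // compact sorted LMS substrings into SA[0..n1-1]
    int n1 = 0;
    for (int i = 0; i < n; ++i)
        if (is_lms(t, SA[i])) SA[n1++] = SA[i];

    // name LMS substrings
    for (int i = n1; i < n; ++i) SA[i] = -1;
    int name = 0, prev = -1;
    for (int i = 0; i < n1; ++i) {
        int pos = SA[i];
        bool diff = false;
        if (prev == -1) diff = true;
        else {
            for (int d = 0; d < n; ++d) {
                if (s[pos + d] != s[prev + d] ||
                    t[pos + d] != t[prev + d]) { diff = true; break; }
                if (d > 0 && (is_lms(t, pos + d) || is_lms(t, prev + d))) {
                    if (!(is_lms(t, pos + d) && is_lms(t, prev + d)))
                        diff = true;
                    break;
                }
            }
        }
        if (diff) { ++name; prev = pos; }
        SA[n1 + pos / 2] = name - 1;
    }
    int j = n - 1;
    for (int i = n - 1; i >= n1; --i)
        if (SA[i] >= 0) SA[j--] = SA[i];

    int *SA1 = SA, *s1 = SA + n - n1;
    if (name < n1) {
        sa_is(s1, SA1, n1, name - 1);
    } else {
        for (int i = 0; i < n1; ++i) SA1[s1[i]] = i;
    }

    // map back to LMS positions and induce the full array
    std::vector<int> lms(n1);
    {
        int k = 0;
        for (int i = 1; i < n; ++i)
            if (is_lms(t, i)) lms[k++] = i;
    }
    for (int i = 0; i < n1; ++i) SA1[i] = lms[SA1[i]];
    for (int i = n1; i < n; ++i) SA[i] = -1;
    get_buckets(s, bkt.data(), n, K, true);
    for (int i = n1 - 1; i >= 0; --i) {
        int pos = SA[i];
        SA[i] = -1;
        SA[--bkt[s[pos]]] = pos;
    }
    induce_l(t, SA, s, bkt.data(), n, K);
    induce_s(t, SA, s, bkt.data(), n, K);
}

} // namespace

// codes: 0-based symbol codes; returns 0-based sa and lcp (lcp[0] = 0,
// lcp[i] = longest common prefix of suffixes sa[i-1] and sa[i])
// [[Rcpp::export]]
List cpp_suffix_index(IntegerVector codes, int m) {
    int n = codes.size();
    if (n < 1) Rcpp::stop("empty sequence");
    std::vector<int> s(n + 1);
    for (int i = 0; i < n; ++i) {
        if (codes[i] < 0 || codes[i] >= m) Rcpp::stop("code out of range");
        s[i] = codes[i] + 1; // reserve 0 for the sentinel
    }
    s[n] = 0;
    std::vector<int> SA(n + 1);
    sa_is(s.data(), SA.data(), n + 1, m);
    IntegerVector sa(n), lcp(n);
    for (int i = 0; i < n; ++i) sa[i] = SA[i + 1]; // drop the sentinel row

    // Kasai
    std::vector<int> rank(n);
    for (int i = 0; i < n; ++i) rank[sa[i]] = i;
    int h = 0;
    for (int i = 0; i < n; ++i) {
        if (rank[i] > 0) {
            int j = sa[rank[i] - 1];
            while (i + h < n && j + h < n && codes[i + h] == codes[j + h]) ++h;
            lcp[rank[i]] = h;
            if (h > 0) --h;
        } else {
            lcp[0] = 0;
            h = 0;
        }
    }
    return List::create(Rcpp::Named("sa") = sa, Rcpp::Named("lcp") = lcp);
}

namespace {
// -1, 0, +1: compare word against the prefix of suffix `pos`
int cmp_suffix(const IntegerVector &codes, int pos, const IntegerVector &w) {
    int n = codes.size(), k = w.size();
    for (int d = 0; d < k; ++d) {
        if (pos + d >= n) return 1;           // suffix ran out: word greater
        if (w[d] != codes[pos + d]) return w[d] < codes[pos + d] ? -1 : 1;
    }
    return 0;
}
} // namespace

// number of (possibly overlapping) occurrences of word, via binary search
// over the suffix array
// [[Rcpp::export]]
int cpp_sa_multiplicity(IntegerVector codes, IntegerVector sa,
                        IntegerVector word) {
    int n = sa.size();
    int lo = 0, hi = n; // first suffix with prefix >= word
    while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cmp_suffix(codes, sa[mid], word) > 0) lo = mid + 1;
        else hi = mid;
    }
    int lo2 = lo, hi2 = n; // first suffix with prefix > word
    while (lo2 < hi2) {
        int mid = (lo2 + hi2) / 2;
        if (cmp_suffix(codes, sa[mid], word) >= 0) lo2 = mid + 1;
        else hi2 = mid;
    }
    return lo2 - lo;
}

// x_{i+1} = (mult * x_i + incr) mod modulus, symbol = floor(m*x_{i+1}/modulus)
// parameters passed as doubles (exact up to 2^53)
// [[Rcpp::export]]
IntegerVector cpp_lcg_codes(double n, int m, double mult, double incr,
                            double modulus, double seed) {
    size_t len = (size_t)n;
    uint64_t a = (uint64_t)mult, b = (uint64_t)incr,
             mod = (uint64_t)modulus, x = (uint64_t)seed % (uint64_t)modulus;
    IntegerVector out(len);
    for (size_t i = 0; i < len; ++i) {
        x = (uint64_t)(((unsigned __int128)a * x + b) % mod);
        out[i] = (int)(((unsigned __int128)m * x) / mod);
    }
    return out;
}
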