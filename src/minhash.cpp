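#include <Rcpp.h>
#include <set>
#include <cstdint>
using namespace Rcpp;

// splitmix64 finalizer; fixed constants define sketch version 1
static inline uint64_t mix64(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
}

static inline int base2bit(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// Bottom-s MinHash sketch over canonical k-mers of a set of sequences.
// Hashes are truncated to 53 bits so they are exactly representable as
// doubles on the R side. k-mers containing non-ACGT letters are skipped.
// [[Rcpp::export(name = ".sketch_cpp")]]
NumericVector sketch_cpp(CharacterVector seqs, int k, int s) {
    if (k < 1 || k > 31) stop("k must be in 1..31");
    if (s < 1) stop("sketch size s must be >= 1");
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
    const uint64_t hmask = (1ULL << 53) - 1ULL;
    std::set<uint64_t> bottom;  // distinct smallest hashes, size-capped at s
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char *str = CHAR(STRING_ELT(seqs, i));
        R_xlen_t n = LENGTH(STRING_ELT(seqs, i));
        if (n < k) continue;
        uint64_t fwd = 0, rev = 0;
        int valid = 0;
        for (R_xlen_t j = 0; j < n; ++j) {
            int b = base2bit(str[j]);
            if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)b) & mask;
            rev = (rev >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
            if (++valid >= k) {
                uint64_t canon = fwd < rev ? fwd : rev;
                uint64_t h = mix64(canon) & hmask;
                if ((int)bottom.size() < s) {
                    bottom.insert(h);
                } else if (h < *bottom.rbegin()) {
                    if (bottom.insert(h).second)
                        bottom.erase(std::prev(bottom.end()));
                }
            }
        }
    }
    NumericVector out(bottom.size());
    R_xlen_t i = 0;
    for (std::set<uint64_t>::iterator it = bottom.begin(); it != bottom.end(); ++it)
        out[i++] = (double)(*it);
    return out;
}
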