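#ifndef BSALIGN3_COMMON_H
#define BSALIGN3_COMMON_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>
#include <utility>

inline int base2bits(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    }
    return -1;
}

inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    }
    return 'N';
}

inline std::string revcomp_str(const std::string &s) {
    std::string out(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i)
        out[s.size() - 1 - i] = comp_base(s[i]);
    return out;
}

// Three-letter index: sorted (packed seed, position) pairs over the
// C2T-converted Watson+Crick concatenation. Lookup by binary search.
struct TLIndex {
    int seed_len;
    std::string concat;
    std::vector<int> block_start;   // per block, into concat
    std::vector<int> block_end;
    std::vector<std::pair<uint64_t, int32_t> > seeds;  // sorted

    // block containing position p, or -1
    int find_block(int p) const {
        if (p < 0 || p >= (int)concat.size()) return -1;
        // blocks are contiguous and sorted
        int lo = 0, hi = (int)block_start.size() - 1;
        while (lo <= hi) {
            int mid = (lo + hi) / 2;
            if (p < block_start[mid]) hi = mid - 1;
            else if (p >= block_end[mid]) lo = mid + 1;
            else return mid;
        }
        return -1;
    }
};

// FNV-1a hash of a string; stable per-read RNG seed
inline uint64_t fnv1a(const std::string &s) {
    uint64_t h = 1469598103934665603ULL;
    for (char c : s) {
        h ^= (uint64_t)(unsigned char)c;
        h *= 1099511628211ULL;
    }
    return h;
}

// splitmix-style deterministic PRNG (independent of R's RNG)
struct SplitMix {
    uint64_t x;
    explicit SplitMix(uint64_t seed) : x(seed) {}
    uint64_t next() {
        uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
    // uniform in [0, n)
    int below(int n) { return (int)(next() % (uint64_t)n); }
};

#endif
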