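#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; 4 = anything that breaks a k-mer (N etc.)
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
    }
}

// Canonical k-mer multiplicity histogram over a set of sequences.
// Rolling 2-bit encoding of the forward k-mer and its reverse complement;
// the canonical form is the numerically smaller of the two. k <= 31 so a
// k-mer fits in 62 bits.
// [[Rcpp::export]]
List kmer_histogram_cpp(CharacterVector seqs, int k) {
    if (k < 1 || k > 31) stop("k must be in 1..31");
    std::unordered_map<uint64_t, uint64_t> counts;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift_rc = 2 * (k - 1);
    uint64_t n_kmers = 0;

    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
        const char *p = CHAR(STRING_ELT(seqs, s));
        uint64_t fwd = 0, rc = 0;
        int run = 0; // valid bases accumulated toward the current k-mer
        for (const char *q = p; *q; ++q) {
            int code = base_code(*q);
            if (code == 4) { run = 0; fwd = 0; rc = 0; continue; }
            fwd = ((fwd << 2) | (uint64_t)code) & mask;
            rc = (rc >> 2) | ((uint64_t)(3 - code) << shift_rc);
            if (++run >= k) {
                uint64_t canon = fwd < rc ? fwd : rc;
                ++counts[canon];
                ++n_kmers;
            }
        }
    }

    // multiplicity -> number of distinct canonical k-mers
    std::unordered_map<uint64_t, uint64_t> hist;
    for (const auto &kv : counts) ++hist[kv.second];
    std::vector<uint64_t> mult;
    mult.reserve(hist.size());
    for (const auto &kv : hist) mult.push_back(kv.first);
    std::sort(mult.begin(), mult.end());
    NumericVector m(mult.size()), cnt(mult.size());
    for (size_t i = 0; i < mult.size(); ++i) {
        m[i] = (double)mult[i];
        cnt[i] = (double)hist[mult[i]];
    }
    return List::create(_["multiplicity"] = m, _["count"] = cnt,
                        _["total_kmers"] = (double)n_kmers);
}
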