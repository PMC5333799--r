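#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// 2-bit packing of a 20-mer over {A,C,G,T}: A=0, C=1, G=2, T=3.
// 40 bits used; XOR of two packed values has a non-zero 2-bit group at
// exactly the mismatching positions, so the Hamming distance is the
// popcount of (x | x>>1) masked to the odd bit lanes.
static const uint64_t ODD_MASK = 0x5555555555555555ULL;

static inline bool pack20(const char *s, uint64_t &out) {
    uint64_t v = 0;
    for (int i = 0; i < 20; ++i) {
        uint64_t code;
        switch (s[i]) {
        case 'A': code = 0; break;
        case 'C': code = 1; break;
        case 'G': code = 2; break;
        case 'T': code = 3; break;
        default: return false;
        }
        v = (v << 2) | code;
    }
    out = v;
    return true;
}

static inline int hamming_packed(uint64_t a, uint64_t b) {
    uint64_t x = a ^ b;
    x = (x | (x >> 1)) & ODD_MASK;
#if defined(__GNUC__) || defined(__clang__)
    return __builtin_popcountll(x);
#else
    int n = 0;
    while (x) { x &= x - 1; ++n; }
    return n;
#endif
}

static std::vector<uint64_t> pack_all(const CharacterVector &seqs,
                                      const char *what) {
    std::vector<uint64_t> out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char *s = CHAR(STRING_ELT(seqs, i));
        if (LENGTH(STRING_ELT(seqs, i)) != 20)
            stop("%s %d is not a 20-mer", what, (int)(i + 1));
        if (!pack20(s, out[i]))
            stop("%s %d contains a non-ACGT character", what, (int)(i + 1));
    }
    return out;
}

// Production route: bit-packed all-pairs counting of genomic sites at
// exact Hamming distance 0..4 from each query 20-mer. Sites are counted
// with multiplicity. Returns an integer matrix |queries| x 5.
// [[Rcpp::export(name = ".mismatchProfilesPacked")]]
IntegerMatrix mismatch_profiles_packed(CharacterVector queries,
                                       CharacterVector sites) {
    std::vector<uint64_t> q = pack_all(queries, "query");
    std::vector<uint64_t> s = pack_all(sites, "site");
    IntegerMatrix out(queries.size(), 5);
    for (size_t i = 0; i < q.size(); ++i) {
        int c[5] = {0, 0, 0, 0, 0};
        const uint64_t qi = q[i];
        for (size_t j = 0; j < s.size(); ++j) {
            int d = hamming_packed(qi, s[j]);
            if (d <= 4) ++c[d];
        }
        for (int k = 0; k < 5; ++k) out(i, k) = c[k];
    }
    return out;
}

// Brute-force oracle route: per-character nested loop, no packing.
// Same contract as the packed route; kept deliberately naive.
// [[Rcpp::export(name = ".mismatchProfilesNaive")]]
IntegerMatrix mismatch_profiles_naive(CharacterVector queries,
                                      CharacterVector sites) {
    R_xlen_t nq = queries.size(), ns = sites.size();
    std::vector<const char *> qp(nq), sp(ns);
    for (R_xlen_t i = 0; i < nq; ++i) {
        if (LENGTH(STRING_ELT(queries, i)) != 20)
            stop("query %d is not a 20-mer", (int)(i + 1));
        qp[i] = CHAR(STRING_ELT(queries, i));
    }
    for (R_xlen_t j = 0; j < ns; ++j) {
        if (LENGTH(STRING_ELT(sites, j)) != 20)
            stop("site %d is not a 20-mer", (int)(j + 1));
        sp[j] = CHAR(STRING_ELT(sites, j));
    }
    IntegerMatrix out(nq, 5);
    for (R_xlen_t i = 0; i < nq; ++i) {
        int c[5] = {0, 0, 0, 0, 0};
        for (R_xlen_t j = 0; j < ns; ++j) {
            int d = 0;
            const char *a = qp[i], *b = sp[j];
            for (int k = 0; k < 20 && d <= 4; ++k)
                if (a[k] != b[k]) ++d;
            if (d <= 4) ++c[d];
        }
        for (int k = 0; k < 5; ++k) out(i, k) = c[k];
    }
    return out;
}

// TRUE for each query with at least one reference 20-mer at Hamming
// distance <= maxMismatch (used for the coding-region exclusion pass).
// [[Rcpp::export(name = ".hasNeighborWithin")]]
LogicalVector has_neighbor_within(CharacterVector queries,
                                  CharacterVector refs, int maxMismatch) {
    std::vector<uint64_t> q = pack_all(queries, "query");
    std::vector<uint64_t> r = pack_all(refs, "reference");
    LogicalVector out(queries.size());
    for (size_t i = 0; i < q.size(); ++i) {
        bool hit = false;
        for (size_t j = 0; j < r.size() && !hit; ++j)
            hit = hamming_packed(q[i], r[j]) <= maxMismatch;
        out[i] = hit;
    }
    return out;
}
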