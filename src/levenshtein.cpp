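#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Two-row dynamic-programming edit distance, unit costs for
// substitution / insertion / deletion.
static int ld_dp(const char *a, int na, const char *b, int nb) {
    if (na == 0) return nb;
    if (nb == 0) return na;
    std::vector<int> prev(nb + 1), cur(nb + 1);
    for (int j = 0; j <= nb; ++j) prev[j] = j;
    for (int i = 1; i <= na; ++i) {
        cur[0] = i;
        for (int j = 1; j <= nb; ++j) {
            const int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
            cur[j] = std::min({prev[j] + 1, cur[j - 1] + 1, prev[j - 1] + cost});
        }
        std::swap(prev, cur);
    }
    return prev[nb];
}

// Textbook exponential recursion; kept deliberately naive so it is an
// algorithmically independent oracle for the DP implementation.
static int ld_rec(const char *a, int na, const char *b, int nb) {
    if (na == 0) return nb;
    if (nb == 0) return na;
    const int cost = (a[na - 1] == b[nb - 1]) ? 0 : 1;
    const int del = ld_rec(a, na - 1, b, nb) + 1;
    const int ins = ld_rec(a, na, b, nb - 1) + 1;
    const int sub = ld_rec(a, na - 1, b, nb - 1) + cost;
    return std::min({del, ins, sub});
}

// [[Rcpp::export(name = ".ld_pairs_cpp")]]
IntegerVector ld_pairs_cpp(CharacterVector a, CharacterVector b) {
    const R_xlen_t n = a.size();
    if (b.size() != n) stop("a and b must have equal length");
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (a[i] == NA_STRING || b[i] == NA_STRING) {
            out[i] = NA_INTEGER;
            continue;
        }
        const char *sa = CHAR(STRING_ELT(a, i));
        const char *sb = CHAR(STRING_ELT(b, i));
        out[i] = ld_dp(sa, (int) LENGTH(STRING_ELT(a, i)),
                       sb, (int) LENGTH(STRING_ELT(b, i)));
    }
    return out;
}

// [[Rcpp::export(name = ".ld_matrix_cpp")]]
IntegerMatrix ld_matrix_cpp(CharacterVector s) {
    const int n = (int) s.size();
    IntegerMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        const char *si = CHAR(STRING_ELT(s, i));
        const int ni = (int) LENGTH(STRING_ELT(s, i));
        for (int j = i + 1; j < n; ++j) {
            const int d = ld_dp(si, ni, CHAR(STRING_ELT(s, j)),
                                (int) LENGTH(STRING_ELT(s, j)));
            out(i, j) = d;
            out(j, i) = d;
        }
    }
    return out;
}

// [[Rcpp::export(name = ".ld_recursive_cpp")]]
int ld_recursive_cpp(std::string a, std::string b) {
    return ld_rec(a.c_str(), (int) a.size(), b.c_str(), (int) b.size());
}

// Compares the DP distance with the naive recursion over every unordered
// pair (including self-pairs) of the supplied strings and returns the
// number of disagreements.
// [[Rcpp::export(name = ".ld_oracle_mismatches")]]
double ld_oracle_mismatches(CharacterVector s) {
    const int n = (int) s.size();
    double bad = 0;
    for (int i = 0; i < n; ++i) {
        const char *si = CHAR(STRING_ELT(s, i));
        const int ni = (int) LENGTH(STRING_ELT(s, i));
        for (int j = i; j < n; ++j) {
            const char *sj = CHAR(STRING_ELT(s, j));
            const int nj = (int) LENGTH(STRING_ELT(s, j));
            if (ld_dp(si, ni, sj, nj) != ld_rec(si, ni, sj, nj)) bad += 1;
        }
    }
    return bad;
}
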