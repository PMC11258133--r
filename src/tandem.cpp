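#include <Rcpp.h>
using namespace Rcpp;

static inline bool is_acgt(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T' ||
           c == 'a' || c == 'c' || c == 'g' || c == 't';
}

// Number of i < L-u with w[i] != w[i+u]; any non-ACGT base mismatches
// everything (so N never supports a period).
static int period_violations(const char *w, int L, int u, int cap) {
    int v = 0;
    for (int i = 0; i + u < L; ++i) {
        if (!is_acgt(w[i]) || !is_acgt(w[i + u]) || w[i] != w[i + u]) {
            if (++v > cap) return v;
        }
    }
    return v;
}

// Smallest exact period of the unit itself (primitivity check).
static int smallest_exact_period(const char *w, int L) {
    for (int u = 1; u <= L / 2; ++u) {
        if (L % u != 0) continue;
        bool ok = true;
        for (int i = 0; i + u < L && ok; ++i)
            if (w[i] != w[i + u]) ok = false;
        if (ok) return u;
    }
    return L;
}

// Tandem-unit detection over fixed-width windows: for each window return the
// smallest period u (scanned from 1 so sub-range periods such as homopolymers
// disqualify the window) together with the copy number floor(L/u). A window
// yields a hit only when the qualifying period lies inside
// [min_len, max_len], the unit is primitive and copies >= min_copies.
// [[Rcpp::export]]
List find_tandem_units_cpp(CharacterVector windows, int min_len, int max_len,
                           int max_mismatch, int min_copies) {
    R_xlen_t n = windows.size();
    CharacterVector unit(n, NA_STRING);
    IntegerVector copies(n, NA_INTEGER);
    for (R_xlen_t j = 0; j < n; ++j) {
        if (windows[j] == NA_STRING) continue;
        const char *w = CHAR(STRING_ELT(windows, j));
        int L = LENGTH(STRING_ELT(windows, j));
        if (L < 2 * min_len) continue;
        int found = -1;
        for (int u = 1; u <= max_len && u <= L / 2; ++u) {
            if (period_violations(w, L, u, max_mismatch) <= max_mismatch) {
                found = u;
                break;
            }
        }
        if (found < min_len || found > max_len) continue;
        int ncopy = L / found;
        if (ncopy < min_copies) continue;
        std::string uu(w, w + found);
        if (smallest_exact_period(uu.c_str(), found) != found) continue;
        unit[j] = uu;
        copies[j] = ncopy;
    }
    return List::create(_["unit"] = unit, _["copies"] = copies);
}
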