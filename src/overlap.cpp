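#include <Rcpp.h>
using namespace Rcpp;

// Longest suffix(a)/prefix(b) match allowing substitutions only.
// Scans overlap lengths from the longest possible downwards and returns the
// first (i.e. longest) length whose mismatch count stays within
// floor(max_mismatch_frac * L).  Early abort once the budget is exceeded
// keeps the scan cheap for unrelated sequences.
static inline void scan_pair(const char *a, int la, const char *b, int lb,
                             int min_overlap, double max_mismatch_frac,
                             int &best_len, int &best_mm) {
    best_len = 0; best_mm = 0;
    int lmax = la < lb ? la : lb;
    for (int L = lmax; L >= min_overlap; --L) {
        int allowed = (int)(max_mismatch_frac * L + 1e-9);
        int mm = 0;
        const char *pa = a + (la - L);
        bool ok = true;
        for (int i = 0; i < L; ++i) {
            if (pa[i] != b[i] && ++mm > allowed) { ok = false; break; }
        }
        if (ok) { best_len = L; best_mm = mm; return; }
    }
}

// [[Rcpp::export]]
IntegerVector overlap_scan_cpp(std::string a, std::string b,
                               int min_overlap, double max_mismatch_frac) {
    if (min_overlap < 1) stop("min_overlap must be >= 1");
    int len, mm;
    scan_pair(a.c_str(), a.size(), b.c_str(), b.size(),
              min_overlap, max_mismatch_frac, len, mm);
    return IntegerVector::create(len, mm);
}

// suffix(a) vs prefix(b_i) for a vector of b's; one row (len, mm) per b.
// [[Rcpp::export]]
IntegerMatrix overlap_scan_suffix_cpp(std::string a, CharacterVector bs,
                                      int min_overlap, double max_mismatch_frac) {
    int n = bs.size();
    IntegerMatrix out(n, 2);
    for (int i = 0; i < n; ++i) {
        std::string b = as<std::string>(bs[i]);
        int len, mm;
        scan_pair(a.c_str(), a.size(), b.c_str(), b.size(),
                  min_overlap, max_mismatch_frac, len, mm);
        out(i, 0) = len; out(i, 1) = mm;
    }
    return out;
}

// suffix(a_i) vs prefix(b) for a vector of a's.
// [[Rcpp::export]]
IntegerMatrix overlap_scan_prefix_cpp(CharacterVector av, std::string b,
                                      int min_overlap, double max_mismatch_frac) {
    int n = av.size();
    IntegerMatrix out(n, 2);
    for (int i = 0; i < n; ++i) {
        std::string a = as<std::string>(av[i]);
        int len, mm;
        scan_pair(a.c_str(), a.size(), b.c_str(), b.size(),
                  min_overlap, max_mismatch_frac, len, mm);
        out(i, 0) = len; out(i, 1) = mm;
    }
    return out;
}
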