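#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Banded global alignment of a vs b (match +1, mismatch -2, gap -3),
// optionally with free end gaps on both sequences (overlap-style ends).
// Returns the score plus the number of matched columns and total aligned
// columns along the optimal path (end overhangs excluded when free_ends),
// which is all that identity assessment needs; no traceback matrix is kept,
// so memory stays O(len(b)) even for chromosome-scale inputs.
// [[Rcpp::export]]
List banded_align_stats_cpp(std::string a, std::string b, int band,
                            bool free_ends) {
    const int la = a.size(), lb = b.size();
    const int MATCH = 1, MISMATCH = -2, GAP = -3;
    const long NEG = LONG_MIN / 4;
    const int d = la - lb;                 // main diagonal drift
    const int lo = (d < 0 ? d : 0) - band; // i - j in [lo, hi]
    const int hi = (d > 0 ? d : 0) + band;

    // three stats per cell: score, matches, columns
    std::vector<long> sc0(lb + 1, NEG), sc1(lb + 1, NEG);
    std::vector<int> mt0(lb + 1, 0), mt1(lb + 1, 0);
    std::vector<int> cl0(lb + 1, 0), cl1(lb + 1, 0);

    for (int j = 0; j <= lb; ++j) {
        if (0 - j < lo || 0 - j > hi) continue;
        sc0[j] = free_ends ? 0 : (long)GAP * j;
        mt0[j] = 0;
        cl0[j] = free_ends ? 0 : j;
    }
    long best_sc = NEG; int best_mt = 0, best_cl = 0;
    if (free_ends && la == 0) { best_sc = 0; }

    for (int i = 1; i <= la; ++i) {
        std::fill(sc1.begin(), sc1.end(), NEG);
        int jmin = i - hi > 0 ? i - hi : 0;
        int jmax = i - lo < lb ? i - lo : lb;
        if (jmin > jmax) break;
        if (jmin == 0) {
            sc1[0] = free_ends ? 0 : (long)GAP * i;
            mt1[0] = 0;
            cl1[0] = free_ends ? 0 : i;
        }
        const char ai = a[i - 1];
        for (int j = jmin > 0 ? jmin : 1; j <= jmax; ++j) {
            long s_diag = sc0[j - 1] == NEG ? NEG
                : sc0[j - 1] + (ai == b[j - 1] ? MATCH : MISMATCH);
            long s_up = sc0[j] == NEG ? NEG : sc0[j] + GAP;     // gap in b
            long s_left = sc1[j - 1] == NEG ? NEG : sc1[j - 1] + GAP; // gap in a
            // prefer diagonal on ties for stable stats
            if (s_diag >= s_up && s_diag >= s_left && s_diag != NEG) {
                sc1[j] = s_diag;
                mt1[j] = mt0[j - 1] + (ai == b[j - 1] ? 1 : 0);
                cl1[j] = cl0[j - 1] + 1;
            } else if (s_up >= s_left && s_up != NEG) {
                sc1[j] = s_up; mt1[j] = mt0[j]; cl1[j] = cl0[j] + 1;
            } else if (s_left != NEG) {
                sc1[j] = s_left; mt1[j] = mt1[j - 1]; cl1[j] = cl1[j - 1] + 1;
            }
            if (free_ends && (i == la || j == lb) && sc1[j] != NEG) {
                if (sc1[j] > best_sc) {
                    best_sc = sc1[j]; best_mt = mt1[j]; best_cl = cl1[j];
                }
            }
        }
        std::swap(sc0, sc1); std::swap(mt0, mt1); std::swap(cl0, cl1);
    }
    if (!free_ends) {
        if (la - lb < lo || la - lb > hi || sc0[lb] == NEG)
            stop("band too narrow for a global alignment");
        best_sc = sc0[lb]; best_mt = mt0[lb]; best_cl = cl0[lb];
    } else if (best_sc == NEG) {
        stop("band too narrow: no path reached an end");
    }
    return List::create(_["score"] = (double)best_sc,
                        _["matches"] = best_mt,
                        _["columns"] = best_cl);
}
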