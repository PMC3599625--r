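#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Indel-tolerant suffix(a)/prefix(b) overlap: the alignment must end at
// a's last base and start at b's first base; a's start and b's end are
// free.  Match +1, mismatch -2, gap -3.  Returns the a-suffix length,
// b-prefix length, edit count and column count of the best-scoring
// qualifying overlap, or zeros when none qualifies.
// [[Rcpp::export]]
List overlap_edit_cpp(std::string a, std::string b, int min_overlap,
                      double max_edit_frac) {
    const int la = a.size(), lb = b.size();
    const int MATCH = 1, MISMATCH = -2, GAP = -3;
    const long NEG = LONG_MIN / 4;
    // dp over a rows (free start), b columns (anchored at 1)
    std::vector<long> sc0(lb + 1), sc1(lb + 1);
    std::vector<int> mt0(lb + 1), mt1(lb + 1), cl0(lb + 1), cl1(lb + 1),
        st0(lb + 1), st1(lb + 1);
    for (int j = 0; j <= lb; ++j) {
        sc0[j] = (long)GAP * j; mt0[j] = 0; cl0[j] = j; st0[j] = 0;
    }
    long best = NEG; int bmt = 0, bcl = 0, bst = 0, bj = 0;
    for (int i = 1; i <= la; ++i) {
        sc1[0] = 0; mt1[0] = 0; cl1[0] = 0; st1[0] = i; // free a start
        const char ai = a[i - 1];
        for (int j = 1; j <= lb; ++j) {
            long s_diag = sc0[j - 1] + (ai == b[j - 1] ? MATCH : MISMATCH);
            long s_up = sc0[j] + GAP;
            long s_left = sc1[j - 1] + GAP;
            if (s_diag >= s_up && s_diag >= s_left) {
                sc1[j] = s_diag;
                mt1[j] = mt0[j - 1] + (ai == b[j - 1] ? 1 : 0);
                cl1[j] = cl0[j - 1] + 1; st1[j] = st0[j - 1];
            } else if (s_up >= s_left) {
                sc1[j] = s_up; mt1[j] = mt0[j]; cl1[j] = cl0[j] + 1;
                st1[j] = st0[j];
            } else {
                sc1[j] = s_left; mt1[j] = mt1[j - 1]; cl1[j] = cl1[j - 1] + 1;
                st1[j] = st1[j - 1];
            }
        }
        std::swap(sc0, sc1); std::swap(mt0, mt1);
        std::swap(cl0, cl1); std::swap(st0, st1);
    }
    for (int j = 1; j <= lb; ++j) {   // free b end
        if (sc0[j] > best) {
            best = sc0[j]; bmt = mt0[j]; bcl = cl0[j]; bst = st0[j]; bj = j;
        }
    }
    int edits = bcl - bmt;
    if (bcl < min_overlap || edits > max_edit_frac * bcl || best <= 0)
        return List::create(_["a_suffix_len"] = 0, _["b_prefix_len"] = 0,
                            _["edits"] = 0, _["columns"] = 0);
    return List::create(_["a_suffix_len"] = la - bst,
                        _["b_prefix_len"] = bj,
                        _["edits"] = edits, _["columns"] = bcl);
}
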