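#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Banded local alignment (Smith-Waterman, single maximal path) of a read
// against a reference window: match +1, mismatch -2, gap -3, zero floor.
// Read bases outside the optimal path are reported as soft clips, so reads
// overhanging the window ends are clipped rather than forced into end
// insertions.  Returns the window span (1-based, inclusive), match and
// column counts of the path, and the read-vs-reference cigar (S/M/I/D).
// [[Rcpp::export]]
List banded_read_align_cpp(std::string read, std::string window, int band) {
    const int la = read.size(), lb = window.size();
    const int MATCH = 1, MISMATCH = -2, GAP = -3;
    // allow diagonals i - j in [lo, hi]: the read may sit anywhere in the
    // window, drifting by at most `band`
    const int lo = (la - lb < 0 ? la - lb : 0) - band;
    const int hi = (la - lb > 0 ? la - lb : 0) + band;

    std::vector<long> sc0(lb + 1, 0), sc1(lb + 1, 0);
    std::vector<unsigned char> tb((size_t)(la + 1) * (lb + 1), 0);
    // tb codes: 0 stop (score floor), 1 diag, 2 up (read-only base, I),
    // 3 left (window-only base, D)

    long best = 0; int bi = 0, bj = 0;
    for (int i = 1; i <= la; ++i) {
        std::fill(sc1.begin(), sc1.end(), 0);
        int jmin = i - hi > 0 ? i - hi : 0;
        int jmax = i - lo < lb ? i - lo : lb;
        if (jmin > jmax) break;
        const char ai = read[i - 1];
        for (int j = jmin > 0 ? jmin : 1; j <= jmax; ++j) {
            long s_diag = sc0[j - 1] + (ai == window[j - 1] ? MATCH : MISMATCH);
            long s_up = sc0[j] + GAP;
            long s_left = sc1[j - 1] + GAP;
            long s; unsigned char t;
            if (s_diag >= s_up && s_diag >= s_left) { s = s_diag; t = 1; }
            else if (s_up >= s_left) { s = s_up; t = 2; }
            else { s = s_left; t = 3; }
            if (s <= 0) { s = 0; t = 0; }
            sc1[j] = s;
            tb[(size_t)i * (lb + 1) + j] = t;
            if (s > best) { best = s; bi = i; bj = j; }
        }
        std::swap(sc0, sc1);
    }
    if (best <= 0)
        return List::create(_["ref_start"] = 0, _["ref_end"] = 0,
                            _["matches"] = 0, _["columns"] = 0,
                            _["score"] = 0.0, _["cigar"] = "");

    // traceback from the best cell to a floor cell
    std::string ops;
    int i = bi, j = bj, matches = 0;
    while (i > 0 && j > 0) {
        unsigned char t = tb[(size_t)i * (lb + 1) + j];
        if (t == 0) break;
        if (t == 1) {
            ops.push_back('M');
            if (read[i - 1] == window[j - 1]) ++matches;
            --i; --j;
        } else if (t == 2) { ops.push_back('I'); --i; }
        else { ops.push_back('D'); --j; }
    }
    const int lead_clip = i;            // read bases before the path
    const int trail_clip = la - bi;     // read bases after the path
    const int ref_start = j + 1, ref_end = bj;

    std::string cigar;
    if (lead_clip > 0) cigar += std::to_string(lead_clip) + "S";
    for (int p = (int)ops.size() - 1; p >= 0;) {
        char op = ops[p]; int run = 0;
        while (p >= 0 && ops[p] == op) { ++run; --p; }
        cigar += std::to_string(run); cigar.push_back(op);
    }
    if (trail_clip > 0) cigar += std::to_string(trail_clip) + "S";

    return List::create(_["ref_start"] = ref_start, _["ref_end"] = ref_end,
                        _["matches"] = matches,
                        _["columns"] = (int)ops.size(),
                        _["read_bases"] = bi - lead_clip,
                        _["score"] = (double)best, _["cigar"] = cigar);
}
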