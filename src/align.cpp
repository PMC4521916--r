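#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Ungapped x-drop extension of an exact word seed.  All coordinates 0-based;
// returned intervals are half-open.  The seed word (length w at qpos/spos) is
// assumed to match exactly.
// [[Rcpp::export(name = ".xdrop_extend_cpp")]]
IntegerVector xdrop_extend_cpp(std::string q, std::string s,
                               int qpos, int spos, int w,
                               int match, int mismatch, int xdrop) {
    const int nq = (int) q.size(), ns = (int) s.size();
    int score = w * match;

    // right extension from the end of the word
    int best = score, run = score;
    int qe = qpos + w, se = spos + w;
    int bqe = qe, bse = se;
    while (qe < nq && se < ns) {
        run += (q[qe] == s[se]) ? match : mismatch;
        ++qe; ++se;
        if (run > best) { best = run; bqe = qe; bse = se; }
        if (best - run > xdrop) break;
    }
    score = best;

    // left extension from the start of the word
    best = score; run = score;
    int qs = qpos, ss = spos;
    int bqs = qs, bss = ss;
    while (qs > 0 && ss > 0) {
        run += (q[qs - 1] == s[ss - 1]) ? match : mismatch;
        --qs; --ss;
        if (run > best) { best = run; bqs = qs; bss = ss; }
        if (best - run > xdrop) break;
    }
    score = best;

    int matches = 0;
    for (int t = 0; t < bqe - bqs; ++t)
        if (q[bqs + t] == s[bss + t]) ++matches;

    return IntegerVector::create(bqs, bqe, bss, bse, score, matches);
}

// Best local alignment (Gotoh affine-gap Smith-Waterman) with traceback.
// A gap of length k costs gap_open + k * gap_extend (both passed as
// non-negative penalties).  Returns score, a/b intervals (0-based half-open),
// match count, alignment length (columns) and number of gap openings.
// [[Rcpp::export(name = ".smith_waterman_cpp")]]
IntegerVector smith_waterman_cpp(std::string a, std::string b,
                                 int match, int mismatch,
                                 int gap_open, int gap_extend) {
    const int n = (int) a.size(), m = (int) b.size();
    const int NEG = -1000000000;
    std::vector< std::vector<int> > H(n + 1, std::vector<int>(m + 1, 0));
    std::vector< std::vector<int> > E(n + 1, std::vector<int>(m + 1, NEG));
    std::vector< std::vector<int> > F(n + 1, std::vector<int>(m + 1, NEG));
    // traceback: tH 0=stop 1=diag 2=fromE(gap in a) 3=fromF(gap in b)
    std::vector< std::vector<char> > tH(n + 1, std::vector<char>(m + 1, 0));
    std::vector< std::vector<char> > tE(n + 1, std::vector<char>(m + 1, 0));
    std::vector< std::vector<char> > tF(n + 1, std::vector<char>(m + 1, 0));

    int bi = 0, bj = 0, bscore = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            // E: gap in a (consume b[j-1])
            int open = H[i][j - 1] - gap_open - gap_extend;
            int ext  = (E[i][j - 1] == NEG) ? NEG : E[i][j - 1] - gap_extend;
            if (open >= ext) { E[i][j] = open; tE[i][j] = 1; }
            else             { E[i][j] = ext;  tE[i][j] = 0; }
            // F: gap in b (consume a[i-1])
            open = H[i - 1][j] - gap_open - gap_extend;
            ext  = (F[i - 1][j] == NEG) ? NEG : F[i - 1][j] - gap_extend;
            if (open >= ext) { F[i][j] = open; tF[i][j] = 1; }
            else             { F[i][j] = ext;  tF[i][j] = 0; }

            int diag = H[i - 1][j - 1] + ((a[i - 1] == b[j - 1]) ? match : mismatch);
            int h = 0; char t = 0;
            if (diag > h)    { h = diag;    t = 1; }
            if (E[i][j] > h) { h = E[i][j]; t = 2; }
            if (F[i][j] > h) { h = F[i][j]; t = 3; }
            H[i][j] = h; tH[i][j] = t;
            if (h > bscore) { bscore = h; bi = i; bj = j; }
        }
    }

    // traceback from the best cell
    int i = bi, j = bj;
    int matches = 0, cols = 0, gap_openings = 0;
    int state = 0;  // 0 = H, 1 = E, 2 = F
    while (i > 0 && j > 0) {
        if (state == 0) {
            char t = tH[i][j];
            if (t == 0) break;
            if (t == 1) {
                if (a[i - 1] == b[j - 1]) ++matches;
                ++cols; --i; --j;
            } else if (t == 2) state = 1;
            else state = 2;
        } else if (state == 1) {
            char t = tE[i][j];
            ++cols; --j;
            if (t == 1) { ++gap_openings; state = 0; }
        } else {
            char t = tF[i][j];
            ++cols; --i;
            if (t == 1) { ++gap_openings; state = 0; }
        }
    }

    return IntegerVector::create(bscore, i, bi, j, bj, matches, cols,
                                 gap_openings);
}
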