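#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair scores for the built-in engine, in arbitrary energy units reported as
// dG: GC -3, AU -2, GU -1.  Returns +1 for a non-pairable combination.
static inline int pair_score(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3;
    if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2;
    if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1;
    return 1;
}

// Minimum-score Nussinov-style fold.  min_hairpin unpaired nucleotides are
// required inside every hairpin loop.  Traceback is deterministic: at (i, j)
// the 5'-most base is paired whenever pairing attains the optimum, to its
// nearest admissible partner.
// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
List nussinov_fold_cpp(std::string seq, int min_hairpin = 3) {
    const int n = (int) seq.size();
    std::string db(n, '.');
    if (n == 0)
        return List::create(_["dotbracket"] = db, _["dG"] = 0.0);

    // W[i][j], 0-based, value 0 for empty/short intervals
    std::vector< std::vector<int> > W(n, std::vector<int>(n, 0));
    auto get = [&](int i, int j) -> int {
        if (i > j || i >= n || j < 0) return 0;
        return W[i][j];
    };

    for (int len = min_hairpin + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = get(i + 1, j);  // i unpaired
            for (int k = i + min_hairpin + 1; k <= j; ++k) {
                int s = pair_score(seq[i], seq[k]);
                if (s > 0) continue;
                int cand = s + get(i + 1, k - 1) + get(k + 1, j);
                if (cand < best) best = cand;
            }
            W[i][j] = best;
        }
    }

    // iterative traceback
    std::vector< std::pair<int,int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j) continue;
        int best = get(i, j);
        bool paired = false;
        for (int k = i + min_hairpin + 1; k <= j; ++k) {
            int s = pair_score(seq[i], seq[k]);
            if (s > 0) continue;
            if (s + get(i + 1, k - 1) + get(k + 1, j) == best) {
                db[i] = '(';
                db[k] = ')';
                stack.push_back(std::make_pair(i + 1, k - 1));
                stack.push_back(std::make_pair(k + 1, j));
                paired = true;
                break;
            }
        }
        if (!paired)
            stack.push_back(std::make_pair(i + 1, j));
    }

    return List::create(_["dotbracket"] = db,
                        _["dG"] = (double) W[0][n - 1]);
}
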